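## Residue-level chemistry: canonical residue sets, donor/acceptor role
## tables, moiety and chain-part partitions, covalent-neighbour maps.
## These tables are the ground truth consumed by detection, edge
## classification and the fixture generator.

#' @name chemistry
#' @title Canonical residue chemistry tables
#' @description
#' Constants describing the residues in scope: the 20 canonical amino
#' acids, the 4 canonical ribonucleotides (rA, rG, rC, rU; PDB residue
#' names `A`, `G`, `C`, `U`) and crystallographic water. Modified
#' residues, DNA, ligands and ions are classified `OTHER` and ignored by
#' the bridge pipeline.
NULL

AMINO_ACIDS_3L <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL")

RIBONUCLEOTIDES <- c("A", "C", "G", "U")

## Display names used in bridge nomenclature (rA ... rU).
NT_DISPLAY <- c(A = "rA", C = "rC", G = "rG", U = "rU")

DEFAULT_WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

RES_CLASSES <- c("AMINO_ACID", "RIBONUCLEOTIDE", "WATER", "OTHER")

## Amino acids whose side chain carries no hydrogen-bonding polar atom
## under the naming scheme's convention (exactly Gly and Leu; the
## portion-count combinatorics of the classification scheme depend on
## this set).
SIDE_CHAIN_INCAPABLE <- c("GLY", "LEU")

#' Classify a residue name
#'
#' Deterministic mapping of a residue name to one of the four residue
#' classes. Only the 20 canonical amino acids, the 4 canonical
#' ribonucleotides and configured water names are recognised; everything
#' else (modified nucleotides such as PSU, DNA residues such as DA,
#' ligands, ions) maps to `OTHER`.
#'
#' @param resName character vector of residue names (PDB convention).
#' @param waterNames character vector of residue names treated as water.
#' @return character vector, one of `"AMINO_ACID"`, `"RIBONUCLEOTIDE"`,
#'   `"WATER"`, `"OTHER"`.
#' @examples
#' classifyResidue(c("HOH", "A", "ALA", "PSU"))
#' @export
classifyResidue <- function(resName, waterNames = DEFAULT_WATER_NAMES) {
  resName <- toupper(trimws(resName))
  out <- rep("OTHER", length(resName))
  out[resName %in% waterNames] <- "WATER"
  out[resName %in% RIBONUCLEOTIDES] <- "RIBONUCLEOTIDE"
  out[resName %in% AMINO_ACIDS_3L] <- "AMINO_ACID"
  out
}

## ---------------------------------------------------------------------
## Donor / acceptor role tables.
## Roles: "donor", "acceptor", "both", "none". Water O is both. His ND1
## and NE2 are treated as both (protonation ambiguity). Cys SG and Met SD
## are included (sulfur-mediated bonds are rare but observed).

.AA_ROLES <- list(
  ALA = c(),
  ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
  ASN = c(ND2 = "donor", OD1 = "acceptor"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  CYS = c(SG = "both"),
  GLN = c(NE2 = "donor", OE1 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  GLY = c(),
  HIS = c(ND1 = "both", NE2 = "both"),
  ILE = c(),
  LEU = c(),
  LYS = c(NZ = "donor"),
  MET = c(SD = "acceptor"),
  PHE = c(),
  PRO = c(),
  SER = c(OG = "both"),
  THR = c(OG1 = "both"),
  TRP = c(NE1 = "donor"),
  TYR = c(OH = "both"),
  VAL = c()
)

.NT_BASE_ROLES <- list(
  A = c(N1 = "acceptor", N3 = "acceptor", N6 = "donor", N7 = "acceptor"),
  G = c(N1 = "donor", N2 = "donor", N3 = "acceptor", N7 = "acceptor",
        O6 = "acceptor"),
  C = c(N3 = "acceptor", N4 = "donor", O2 = "acceptor"),
  U = c(N3 = "donor", O2 = "acceptor", O4 = "acceptor")
)

## Sugar/phosphate roles common to the four ribonucleotides.
.NT_BACKBONE_ROLES <- c(
  "OP1" = "acceptor", "OP2" = "acceptor", "OP3" = "acceptor",
  "O5'" = "acceptor", "O4'" = "acceptor", "O3'" = "acceptor",
  "O2'" = "both"
)

#' Hydrogen-bond donor/acceptor roles of a residue's atoms
#'
#' Returns the role table used by [detectHBonds()]: for each polar heavy
#' atom of the residue, whether it can act as a hydrogen-bond donor,
#' acceptor, or both. Water oxygen is both. Backbone amide N is a donor
#' (none for Pro), carbonyl O and terminal OXT are acceptors.
#'
#' @param resName single residue name (e.g. `"ARG"`, `"A"`, `"HOH"`).
#' @param waterNames residue names treated as water.
#' @return named character vector mapping atom name to role; atoms not
#'   listed have role `"none"`.
#' @examples
#' donorAcceptorRoles("HOH")   # O is both
#' donorAcceptorRoles("A")[["N7"]]  # acceptor
#' @export
donorAcceptorRoles <- function(resName, waterNames = DEFAULT_WATER_NAMES) {
  resName <- toupper(trimws(resName))
  cls <- classifyResidue(resName, waterNames)
  if (cls == "WATER") return(c(O = "both"))
  if (cls == "AMINO_ACID") {
    bb <- c(O = "acceptor", OXT = "acceptor")
    if (resName != "PRO") bb <- c(N = "donor", bb)
    return(c(bb, .AA_ROLES[[resName]]))
  }
  if (cls == "RIBONUCLEOTIDE") {
    return(c(.NT_BASE_ROLES[[resName]], .NT_BACKBONE_ROLES))
  }
  stats::setNames(character(0), character(0))
}

## ---------------------------------------------------------------------
## Moiety partition of ribonucleotide atoms.
## Ph = {P, OP1, OP2, OP3, O5'} : the phosphate and its ester oxygen.
## Rb = {C1'..C5', O2', O3', O4'} : the ribose; O3' rides with the sugar
##      because the O2'+O3' combination is ribose-sugar mediated.
## Nb = everything on the base.

.PH_ATOMS <- c("P", "OP1", "OP2", "OP3", "O5'")
.RB_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O2'", "O3'", "O4'")

.NT_BASE_ATOMS <- list(
  A = c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8", "N9"),
  G = c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6", "N7", "C8", "N9"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

#' Moiety of a ribonucleotide atom
#'
#' Partitions every atom of a canonical ribonucleotide into nucleobase
#' (`Nb`), phosphate (`Ph`) or ribose (`Rb`). The phosphate group is
#' `P, OP1, OP2, OP3, O5'`; the ribose is the sugar carbons plus
#' `O2', O3', O4'` (`O3'` belongs to the sugar: an `O2'`+`O3'` contact is
#' ribose-sugar mediated). Atoms outside the residue's chemical graph
#' return `"UNKNOWN_ATOM"`.
#'
#' @param resName ribonucleotide residue name (`"A"`, `"C"`, `"G"`, `"U"`,
#'   optionally prefixed `"r"`).
#' @param atomName atom name(s), canonical ASCII-prime convention.
#' @return character vector over `{"Nb","Ph","Rb","UNKNOWN_ATOM"}`.
#' @examples
#' moietyOf("A", c("OP1", "N7", "O2'"))
#' @export
moietyOf <- function(resName, atomName) {
  resName <- toupper(sub("^r", "", trimws(resName)[1]))
  if (!resName %in% RIBONUCLEOTIDES)
    stop("moietyOf() expects a canonical ribonucleotide, got '", resName, "'")
  atomName <- canonicalAtomName(atomName)
  out <- rep("UNKNOWN_ATOM", length(atomName))
  out[atomName %in% .PH_ATOMS] <- "Ph"
  out[atomName %in% .RB_ATOMS] <- "Rb"
  out[atomName %in% .NT_BASE_ATOMS[[resName]]] <- "Nb"
  out
}

#' Chain part (main/side) of an amino-acid atom
#'
#' Backbone atoms `N`, `CA`, `C`, `O` (and terminal `OXT`) are main chain
#' (`"m"`); every other atom is side chain (`"s"`). Under the naming
#' scheme's convention only Gly and Leu lack a hydrogen-bonding
#' side-chain portion.
#'
#' @param resName amino-acid residue name (3-letter).
#' @param atomName atom name(s).
#' @return character vector over `{"m","s"}`.
#' @examples
#' chainPartOf("SER", c("O", "OG"))
#' @export
chainPartOf <- function(resName, atomName) {
  resName <- toupper(trimws(resName))[1]
  if (!resName %in% AMINO_ACIDS_3L)
    stop("chainPartOf() expects a canonical amino acid, got '", resName, "'")
  atomName <- canonicalAtomName(atomName)
  ifelse(atomName %in% c("N", "CA", "C", "O", "OXT"), "m", "s")
}

## ---------------------------------------------------------------------
## Covalent neighbours of polar atoms (within-residue), used to derive
## the outward direction of a contact atom (fixture placement) and to
## position idealized hydrogens for fixed-geometry donors.

.NEIGHBOURS <- list(
  AA = list(
    N = c("CA"), O = c("C"), OXT = c("C"),
    OG = c("CB"), OG1 = c("CB"), SG = c("CB"), OH = c("CZ"),
    NZ = c("CE"),
    ND2 = c("CG"), OD1 = c("CG"), OD2 = c("CG"),
    NE2.GLN = c("CD"), OE1 = c("CD"), OE2 = c("CD"),
    NE = c("CD", "CZ"), NH1 = c("CZ"), NH2 = c("CZ"),
    ND1 = c("CG", "CE1"), NE2.HIS = c("CD2", "CE1"),
    NE1 = c("CD1", "CE2"), SD = c("CG", "CE")
  ),
  NT = list(
    N1.pur = c("C2", "C6"), N3.pur = c("C2", "C4"), N7 = c("C5", "C8"),
    N6 = c("C6"), O6 = c("C6"), N2 = c("C2"),
    N1.pyr = c("C2", "C6"), N3.pyr = c("C2", "C4"),
    O2 = c("C2"), O4 = c("C4"), N4 = c("C4"), N9 = c("C4", "C8"),
    "O2'" = c("C2'"), "O3'" = c("C3'"), "O4'" = c("C1'", "C4'"),
    "O5'" = c("C5'", "P"), OP1 = c("P"), OP2 = c("P"), OP3 = c("P")
  )
)

## Resolve the covalent neighbours of (resName, atomName); returns
## character(0) when unknown.
atomNeighbours <- function(resName, atomName) {
  resName <- toupper(trimws(resName))
  atomName <- canonicalAtomName(atomName)
  if (resName %in% AMINO_ACIDS_3L) {
    key <- atomName
    if (atomName == "NE2") key <- if (resName == "HIS") "NE2.HIS" else "NE2.GLN"
    nb <- .NEIGHBOURS$AA[[key]]
    return(if (is.null(nb)) character(0) else nb)
  }
  nt <- sub("^r", "", resName)
  if (nt %in% RIBONUCLEOTIDES) {
    key <- atomName
    if (atomName %in% c("N1", "N3"))
      key <- paste0(atomName, if (nt %in% c("A", "G")) ".pur" else ".pyr")
    nb <- .NEIGHBOURS$NT[[key]]
    return(if (is.null(nb)) character(0) else nb)
  }
  character(0)
}

## Donor atoms whose hydrogens are rotatable (position underdetermined
## from heavy atoms): hydroxyls, sulfhydryl, lysine ammonium, water.
## These get distance-only treatment even in with_hydrogens mode.
.ROTATABLE_DONORS <- c("OG", "OG1", "OH", "SG", "NZ", "O2'")

isRotatableDonor <- function(resClass, atomName) {
  resClass == "WATER" | atomName %in% .ROTATABLE_DONORS
}
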