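#' @import methods
NULL

## ---------------------------------------------------------------------
## HBondCriteria

#' Geometric hydrogen-bond criteria
#'
#' Holds the three geometric cutoffs used to call a hydrogen bond:
#' donor-heteroatom to acceptor-heteroatom distance (`maxDA`, default
#' 3.35 Angstrom), hydrogen-acceptor distance (`maxHA`, default 2.7
#' Angstrom) and minimum donor-hydrogen-acceptor angle (`minDHA`,
#' default 90 degrees). The defaults eliminate serendipitous
#' long-distance contacts while retaining bent bonds.
#'
#' @slot maxDA numeric(1), Angstrom.
#' @slot maxHA numeric(1), Angstrom; must be smaller than `maxDA`.
#' @slot minDHA numeric(1), degrees.
#' @export
setClass("HBondCriteria",
         representation(maxDA = "numeric", maxHA = "numeric",
                        minDHA = "numeric"),
         prototype(maxDA = 3.35, maxHA = 2.7, minDHA = 90))

setValidity("HBondCriteria", function(object) {
  msg <- character(0)
  for (s in c("maxDA", "maxHA", "minDHA")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msg <- c(msg, paste0(s, " must be a single positive finite number"))
  }
  if (length(msg) == 0 && object@maxHA >= object@maxDA)
    msg <- c(msg, "maxHA must be smaller than maxDA")
  if (length(msg)) msg else TRUE
})

#' @describeIn HBondCriteria-class Constructor.
#' @param maxDA,maxHA,minDHA the three cutoffs (Angstrom, Angstrom,
#'   degrees).
#' @return an `HBondCriteria` object.
#' @examples
#' hbondCriteria()
#' hbondCriteria(maxDA = 3.5)
#' @export
hbondCriteria <- function(maxDA = 3.35, maxHA = 2.7, minDHA = 90) {
  new("HBondCriteria", maxDA = as.numeric(maxDA), maxHA = as.numeric(maxHA),
      minDHA = as.numeric(minDHA))
}

setMethod("show", "HBondCriteria", function(object) {
  cat(sprintf(
    "HBondCriteria: D-A <= %.2f A, H-A <= %.2f A, D-H-A >= %.0f deg\n",
    object@maxDA, object@maxHA, object@minDHA))
})

## ---------------------------------------------------------------------
## RnpStructure

#' Parsed crystal structure of an RNA-protein complex
#'
#' One model of a crystal structure, held as a flat atom table with
#' residues classified into amino acid / ribonucleotide / water / other.
#' Atom names follow the canonical ASCII-prime convention (`O2'`), altloc
#' has been resolved to a single conformer per atom, and hydrogens from
#' the input file are dropped (geometry is evaluated on heavy atoms).
#'
#' The `atoms` slot is a data.frame with columns `chain`, `resno`
#' (integer), `ins` (insertion code, `""` if none), `resname`, `resclass`,
#' `resid` (unique residue key `chain/resno[ins]/resname`), `atom`,
#' `elem`, `x`, `y`, `z`, `b`, `occ`.
#'
#' @slot pdbId character identifier.
#' @slot modelIndex integer, the model retained.
#' @slot atoms data.frame as described above.
#' @slot resolution numeric, Angstrom (`NA` if unknown).
#' @export
setClass("RnpStructure",
         representation(pdbId = "character", modelIndex = "integer",
                        atoms = "data.frame", resolution = "numeric"),
         prototype(pdbId = "unknown", modelIndex = 1L,
                   resolution = NA_real_))

.ATOM_COLS <- c("chain", "resno", "ins", "resname", "resclass", "resid",
                "atom", "elem", "x", "y", "z", "b", "occ")

setValidity("RnpStructure", function(object) {
  a <- object@atoms
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atoms table must have columns:",
                 paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(a)) {
    if (anyNA(a[, c("x", "y", "z")]) ||
        !all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      return("atom coordinates must be finite")
    if (any(a$b < 0, na.rm = TRUE)) return("B-factors must be >= 0")
    if (any(a$occ <= 0 | a$occ > 1, na.rm = TRUE))
      return("occupancies must lie in (0, 1]")
    if (anyDuplicated(paste(a$resid, a$atom)))
      return("duplicate (residue, atom) entries after altloc resolution")
  }
  TRUE
})

#' @rdname RnpStructure-class
#' @param object an `RnpStructure`.
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname RnpStructure-class
#' @export
setMethod("atoms", "RnpStructure", function(object) object@atoms)

#' @rdname RnpStructure-class
#' @export
setGeneric("pdbId", function(object) standardGeneric("pdbId"))

#' @rdname RnpStructure-class
#' @export
setMethod("pdbId", "RnpStructure", function(object) object@pdbId)

#' Residue-level view of a structure
#'
#' @param object an `RnpStructure`.
#' @return data.frame with one row per residue: `resid`, `chain`,
#'   `resno`, `ins`, `resname`, `resclass`, `natoms`.
#' @export
setGeneric("residueTable", function(object) standardGeneric("residueTable"))

#' @rdname residueTable
#' @export
setMethod("residueTable", "RnpStructure", function(object) {
  a <- object@atoms
  if (!nrow(a))
    return(data.frame(resid = character(0), chain = character(0),
                      resno = integer(0), ins = character(0),
                      resname = character(0), resclass = character(0),
                      natoms = integer(0)))
  idx <- !duplicated(a$resid)
  out <- a[idx, c("resid", "chain", "resno", "ins", "resname", "resclass")]
  out$natoms <- as.integer(table(a$resid)[out$resid])
  rownames(out) <- NULL
  out
})

setMethod("show", "RnpStructure", function(object) {
  rt <- residueTable(object)
  cat(sprintf("RnpStructure '%s' (model %d): %d atoms, %d residues\n",
              object@pdbId, object@modelIndex, nrow(object@atoms), nrow(rt)))
  if (nrow(rt)) {
    tab <- table(factor(rt$resclass, levels = RES_CLASSES))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
})

## ---------------------------------------------------------------------
## WaterBridge / WaterBridgeSet

#' A water-mediated bridge between protein and RNA
#'
#' One crystallographic water hydrogen-bonded to at least one amino acid
#' and at least one ribonucleotide, together with the induced multiplet
#' graph. The order of the multiplet is the number of participating
#' residues plus the central water and equals the water node's degree
#' plus one. A bridge is cyclic when a direct protein-RNA hydrogen bond
#' exists between two of its members.
#'
#' @slot water residue key of the bridging water.
#' @slot waterB numeric, B-factor of the water oxygen.
#' @slot aaMembers,ntMembers character vectors of member residue keys.
#' @slot waterBonds data.frame of hydrogen bonds incident to the water.
#' @slot directBonds data.frame of protein-RNA bonds among members.
#' @slot degree integer, distinct member residues bonded to the water.
#' @slot order integer, `degree + 1`.
#' @slot label character, `"A<a>:w:N<n>"` with `"cyc-"` prefix if cyclic.
#' @slot cyclic logical.
#' @slot overTetrahedral logical, water forms more than four hydrogen
#'   bonds (retained, flagged).
#' @export
setClass("WaterBridge",
         representation(water = "character", waterB = "numeric",
                        aaMembers = "character", ntMembers = "character",
                        waterBonds = "data.frame",
                        directBonds = "data.frame",
                        degree = "integer", order = "integer",
                        label = "character", cyclic = "logical",
                        overTetrahedral = "logical"))

setValidity("WaterBridge", function(object) {
  if (!length(object@aaMembers) || !length(object@ntMembers))
    return("a bridge needs at least one amino acid and one ribonucleotide")
  a <- length(object@aaMembers); n <- length(object@ntMembers)
  if (object@order != a + n + 1L)
    return("order must equal |aaMembers| + |ntMembers| + 1")
  if (object@order != object@degree + 1L)
    return("order must equal water-node degree + 1")
  want <- paste0(if (object@cyclic) "cyc-" else "", "A", a, ":w:N", n)
  if (object@label != want)
    return(sprintf("label '%s' does not match members ('%s')",
                   object@label, want))
  if (object@cyclic != (nrow(object@directBonds) > 0))
    return("cyclic flag must mirror presence of direct member bonds")
  TRUE
})

setMethod("show", "WaterBridge", function(object) {
  cat(sprintf("WaterBridge %s [%s] water=%s (B=%.1f)%s\n  aa: %s\n  nt: %s\n",
              object@label, if (object@cyclic) "cyclic" else "acyclic",
              object@water, object@waterB,
              if (object@overTetrahedral) " over-tetrahedral" else "",
              paste(object@aaMembers, collapse = ", "),
              paste(object@ntMembers, collapse = ", ")))
})

#' Set of water bridges found in one structure
#'
#' Container returned by [surveyStructure()]: the per-water bridges in
#' deterministic (chain, residue number) order plus the survey context
#' needed downstream (all detected hydrogen bonds, the B-factors of every
#' water oxygen in the model, and the structure identifier).
#'
#' @slot structureId character.
#' @slot bridges list of [WaterBridge-class] objects.
#' @slot hbonds data.frame of all detected hydrogen bonds.
#' @slot waterB named numeric, B-factor of every water O in the model.
#' @export
setClass("WaterBridgeSet",
         representation(structureId = "character", bridges = "list",
                        hbonds = "data.frame", waterB = "numeric"))

setValidity("WaterBridgeSet", function(object) {
  if (!all(vapply(object@bridges, is, logical(1), class2 = "WaterBridge")))
    return("bridges must all be WaterBridge objects")
  w <- vapply(object@bridges, function(b) b@water, character(1))
  if (anyDuplicated(w)) return("one bridge per bridging water")
  TRUE
})

#' @param x a `WaterBridgeSet`.
#' @rdname WaterBridgeSet-class
#' @export
setMethod("length", "WaterBridgeSet", function(x) length(x@bridges))

#' @param i index.
#' @rdname WaterBridgeSet-class
#' @export
setMethod("[[", "WaterBridgeSet", function(x, i) x@bridges[[i]])

#' @rdname WaterBridgeSet-class
#' @export
setGeneric("bridges", function(object) standardGeneric("bridges"))

#' @rdname WaterBridgeSet-class
#' @param object a `WaterBridgeSet`.
#' @export
setMethod("bridges", "WaterBridgeSet", function(object) object@bridges)

setMethod("show", "WaterBridgeSet", function(object) {
  labs <- vapply(object@bridges, function(b) b@label, character(1))
  cat(sprintf("WaterBridgeSet '%s': %d bridge(s), %d water(s) in model\n",
              object@structureId, length(labs), length(object@waterB)))
  if (length(labs)) {
    tab <- sort(table(labs), decreasing = TRUE)
    cat("  ", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
})

## ---------------------------------------------------------------------
## EdgeAssignment

#' Moiety and nucleobase-edge assignment of a water-ribonucleotide contact
#'
#' For one (bridging water, ribonucleotide) contact: the interacting
#' atoms, the moiety (nucleobase `Nb`, phosphate `Ph`, ribose `Rb`), the
#' nucleobase edge (Watson-Crick `WC`, Hoogsteen `HG`, Sugar `SG`, or
#' `NONE`) and the rule that decided it (`pair_list`,
#' `unambiguous_single`, `distance_rule`, `ribose_rule`, `moiety_rule`,
#' or `unclassified`).
#'
#' @slot nucleotide residue key.
#' @slot resname ribonucleotide name (`A`/`C`/`G`/`U`).
#' @slot intAtoms sorted character vector of interacting atom names.
#' @slot moiety one of `Nb`, `Ph`, `Rb`.
#' @slot edge one of `WC`, `HG`, `SG`, `NONE`.
#' @slot method decision rule applied.
#' @export
setClass("EdgeAssignment",
         representation(nucleotide = "character", resname = "character",
                        intAtoms = "character", moiety = "character",
                        edge = "character", method = "character"))

setValidity("EdgeAssignment", function(object) {
  if (!object@moiety %in% c("Nb", "Ph", "Rb"))
    return("moiety must be Nb, Ph or Rb")
  if (!object@edge %in% c("WC", "HG", "SG", "NONE"))
    return("edge must be WC, HG, SG or NONE")
  ## edge semantics belong to the nucleobase, except O2' alone which is
  ## ribose moiety carrying SG-edge semantics.
  if (object@edge != "NONE" && object@moiety == "Ph")
    return("phosphate contacts carry no edge")
  TRUE
})

setMethod("show", "EdgeAssignment", function(object) {
  cat(sprintf("EdgeAssignment %s [%s] atoms={%s} moiety=%s edge=%s (%s)\n",
              object@nucleotide, object@resname,
              paste(object@intAtoms, collapse = ","), object@moiety,
              object@edge, object@method))
})

## ---------------------------------------------------------------------
## SurveySummary

#' Aggregated water-bridge survey statistics
#'
#' Produced by [aggregateSurvey()]. Residue-level tables count hydrogen
#' bonds (one water-to-residue-atom bond is one count); topology tables
#' count bridges; B-factor means weight each water oxygen once.
#'
#' @slot nStructures,nWatersTotal,nBridgingWaters,nBridges integers.
#' @slot bondsByNucleotide data.frame (nt, count, pct).
#' @slot bondsByMoiety data.frame (moiety, count, pct).
#' @slot bondsByAminoAcid data.frame (aa, count, pct).
#' @slot bondsByChainPart data.frame (part, count, pct).
#' @slot pairMatrix 20 x 4 matrix of (amino acid, ribonucleotide)
#'   co-membership counts.
#' @slot topologyFreq data.frame (label, cyclic, count).
#' @slot bfactorStats data.frame (statistic, value).
#' @export
setClass("SurveySummary",
         representation(nStructures = "integer", nWatersTotal = "integer",
                        nBridgingWaters = "integer", nBridges = "integer",
                        bondsByNucleotide = "data.frame",
                        bondsByMoiety = "data.frame",
                        bondsByAminoAcid = "data.frame",
                        bondsByChainPart = "data.frame",
                        pairMatrix = "matrix",
                        topologyFreq = "data.frame",
                        bfactorStats = "data.frame"))

setMethod("show", "SurveySummary", function(object) {
  cat(sprintf(paste0(
    "SurveySummary: %d structure(s), %d water(s), ",
    "%d bridging water(s), %d bridge(s)\n"),
    object@nStructures, object@nWatersTotal, object@nBridgingWaters,
    object@nBridges))
  if (nrow(object@topologyFreq)) {
    cat("  topologies:\n")
    print(object@topologyFreq, row.names = FALSE)
  }
})
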