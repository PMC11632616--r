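## Bridging-water identification and multiplet-graph construction.
## A water bridge is a single crystallographic water hydrogen-bonded to
## at least one amino acid and at least one ribonucleotide; its
## multiplet order is the number of participating residues plus one and
## equals the water node's degree plus one.

## Long view of water-incident bonds: one row per (water, partner) bond.
.waterIncidence <- function(hbonds) {
  idx <- which(hbonds$kind %in% c("WATER_RNA", "WATER_PROTEIN"))
  wb <- hbonds[idx, , drop = FALSE]
  if (!nrow(wb))
    return(data.frame(water = character(0), partner = character(0),
                      partner_name = character(0),
                      partner_class = character(0),
                      partner_atom = character(0),
                      water_atom = character(0), row = integer(0)))
  donIsWater <- wb$don_class == "WATER"
  data.frame(
    water = ifelse(donIsWater, wb$don_resid, wb$acc_resid),
    partner = ifelse(donIsWater, wb$acc_resid, wb$don_resid),
    partner_name = ifelse(donIsWater, wb$acc_resname, wb$don_resname),
    partner_class = ifelse(donIsWater, wb$acc_class, wb$don_class),
    partner_atom = ifelse(donIsWater, wb$acc_atom, wb$don_atom),
    water_atom = ifelse(donIsWater, wb$don_atom, wb$acc_atom),
    row = idx,
    stringsAsFactors = FALSE)
}

#' Find bridging waters
#'
#' A bridging water appears in both the water-RNA and the water-protein
#' hydrogen-bond lists: it forms at least one bond with a ribonucleotide
#' and at least one with an amino acid.
#'
#' @param hbonds bond table from [detectHBonds()] or [readHB2()].
#' @return sorted character vector of water residue keys.
#' @examples
#' findBridgingWaters(data.frame()[0, ])  # empty in, empty out
#' @export
findBridgingWaters <- function(hbonds) {
  if (!nrow(hbonds)) return(character(0))
  inc <- .waterIncidence(hbonds)
  wRNA <- unique(inc$water[inc$partner_class == "RIBONUCLEOTIDE"])
  wPro <- unique(inc$water[inc$partner_class == "AMINO_ACID"])
  sort(intersect(wRNA, wPro))
}

#' Build the multiplet graph around one bridging water
#'
#' Collects the water's hydrogen-bonded amino-acid and ribonucleotide
#' residues (multiple bonds from one residue collapse to one member but
#' every bond is retained), the direct protein-RNA bonds among those
#' members, and derives degree, order, the `A_a:w:N_n` topology label
#' and the cyclic flag (cyclic iff at least one direct member-member
#' bond exists). Waters with more than four hydrogen bonds are retained
#' and flagged `overTetrahedral`.
#'
#' @param water residue key of a bridging water.
#' @param hbonds bond table covering the structure.
#' @param waterB B-factor of the water oxygen (optional, for reporting).
#' @return a [WaterBridge-class].
#' @export
buildBridge <- function(water, hbonds, waterB = NA_real_) {
  inc <- .waterIncidence(hbonds)
  mine <- inc[inc$water == water, , drop = FALSE]
  aa <- sort(unique(mine$partner[mine$partner_class == "AMINO_ACID"]))
  nt <- sort(unique(mine$partner[mine$partner_class == "RIBONUCLEOTIDE"]))
  if (!length(aa) || !length(nt))
    stop("'", water, "' is not a bridging water (needs >=1 amino-acid ",
         "and >=1 ribonucleotide hydrogen bond)")
  waterBonds <- hbonds[mine$row, , drop = FALSE]
  rownames(waterBonds) <- NULL
  members <- c(aa, nt)
  direct <- hbonds[hbonds$kind == "PROTEIN_RNA" &
                   hbonds$don_resid %in% members &
                   hbonds$acc_resid %in% members, , drop = FALSE]
  rownames(direct) <- NULL
  cyclic <- nrow(direct) > 0
  degree <- length(members)
  new("WaterBridge", water = water, waterB = as.numeric(waterB),
      aaMembers = aa, ntMembers = nt, waterBonds = waterBonds,
      directBonds = direct, degree = as.integer(degree),
      order = as.integer(degree + 1L),
      label = paste0(if (cyclic) "cyc-" else "",
                     "A", length(aa), ":w:N", length(nt)),
      cyclic = cyclic, overTetrahedral = nrow(waterBonds) > 4)
}

#' Survey one structure for water bridges
#'
#' Full per-structure pipeline: detect hydrogen bonds (or use a
#' supplied bond table, e.g. from [readHB2()]), identify bridging
#' waters, and build one [WaterBridge-class] per bridging water, in
#' deterministic (chain, residue number) order.
#'
#' @param structure an [RnpStructure-class].
#' @param criteria an [HBondCriteria-class].
#' @param mode detection mode, see [detectHBonds()].
#' @param hbonds optional pre-computed bond table; when given, detection
#'   is skipped.
#' @param waterNames residue names treated as water.
#' @return a [WaterBridgeSet-class].
#' @examples
#' mf <- fixtureManifest(list(bridgeSpec("A1:w:N1")), seed = 11)
#' fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
#' surveyStructure(readStructure(fx$path))
#' @export
surveyStructure <- function(structure, criteria = hbondCriteria(),
                            mode = "heavy_atom", hbonds = NULL,
                            waterNames = DEFAULT_WATER_NAMES) {
  if (is.null(hbonds))
    hbonds <- detectHBonds(structure, criteria, mode, waterNames)
  a <- atoms(structure)
  watO <- a[a$resclass == "WATER" & a$elem == "O", , drop = FALSE]
  waterB <- stats::setNames(watO$b, watO$resid)
  ws <- findBridgingWaters(hbonds)
  if (length(ws)) {
    ord <- match(ws, watO$resid)
    ws <- ws[order(watO$chain[ord], watO$resno[ord], watO$ins[ord])]
  }
  br <- lapply(ws, function(w)
    buildBridge(w, hbonds, waterB = unname(waterB[w])))
  new("WaterBridgeSet", structureId = pdbId(structure), bridges = br,
      hbonds = hbonds, waterB = waterB)
}

#' Theoretical class counts for nucleobase-mediated triplet bridges
#'
#' Pure combinatorics of the classification scheme for `A1:w:N1` (and
#' its cyclic counterpart, which has identical counts): 4 nucleobases x
#' 3 edges x (18 amino acids x 2 portions + 2 amino acids x 1 portion)
#' single-portion classes, plus 4 x 3 x 18 dual-portion (`ms`) classes.
#' Under the scheme's convention exactly Gly and Leu lack a
#' hydrogen-bonding side-chain portion.
#'
#' @param topology currently `"A1wN1"` (alias `"A1:w:N1"`).
#' @param cyclic logical; counts are identical for both values.
#' @return list with `single_portion`, `dual_portion`, `total`.
#' @examples
#' enumerateTheoreticalClasses()  # 456 / 216 / 672
#' @export
enumerateTheoreticalClasses <- function(topology = "A1wN1",
                                        cyclic = FALSE) {
  if (!gsub(":", "", topology) %in% c("A1wN1", "cyc-A1wN1"))
    stop("class enumeration is defined for the A1:w:N1 topology")
  nNb <- length(RIBONUCLEOTIDES)
  nEdges <- 3L                                # WC, HG, SG
  nCapable <- length(AMINO_ACIDS_3L) - length(SIDE_CHAIN_INCAPABLE)
  nIncapable <- length(SIDE_CHAIN_INCAPABLE)
  single <- nNb * nEdges * (nCapable * 2L + nIncapable * 1L)
  dual <- nNb * nEdges * nCapable
  list(single_portion = single, dual_portion = dual,
       total = single + dual)
}
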