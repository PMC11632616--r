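## Nucleobase-edge assignment of water-ribonucleotide contacts.
## Two-atom contacts are decided by residue-aware pair lists (WC:
## [N1,N6],[N1,N2],[N1,O6],[N3,N4],[N3,O2],[N3,O4]; HG: [N6,N7],[N7,O6];
## SG: [N3,N9],[N3,O2'],[N1,O2],[N2,N3],[O2,O2']). Single atoms are
## either unambiguous (e.g. purine N1 -> WC, N7 -> HG) or decided by the
## Euclidean distance from the water oxygen to the two atoms adjacent to
## the contact atom (e.g. rA N6: nearer N1 -> WC, else HG). O2' alone
## carries SG-edge semantics; O2' together with O3' is ribose-sugar
## mediated.

.edgeTablesCache <- new.env(parent = emptyenv())

#' Edge-rule tables
#'
#' Loads the nucleobase-edge rule tables (pair list, unambiguous
#' singles, ambiguous singles with their adjacent-atom disambiguation)
#' from a human-readable TSV. The shipped table reconstructs the
#' published rules; pass `path` to substitute an amended table without
#' code changes.
#'
#' @param path optional TSV path; default is the table shipped with the
#'   package.
#' @return list with data.frames `pairs` (resname, atom1, atom2, edge),
#'   `singles` (resname, atom, edge) and `ambiguous` (resname, atom,
#'   adj1, edge1, adj2, edge2).
#' @examples
#' str(edgePairTables())
#' @export
edgePairTables <- function(path = NULL) {
  useCache <- is.null(path)
  if (useCache && !is.null(.edgeTablesCache$tables))
    return(.edgeTablesCache$tables)
  if (is.null(path))
    path <- system.file("extdata", "edge_rules.tsv", package = "HydroBridge",
                        mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  pairs <- raw[raw$type == "pair", c("resname", "atom1", "atom2", "edge")]
  singles <- raw[raw$type == "single", c("resname", "atom1", "edge")]
  names(singles)[2] <- "atom"
  amb <- raw[raw$type == "ambiguous",
             c("resname", "atom1", "adj1", "edge1", "adj2", "edge2")]
  names(amb)[2] <- "atom"
  ## pair lists must be mutually disjoint; single tables must not overlap
  pk <- apply(pairs[, c("resname", "atom1", "atom2")], 1, paste,
              collapse = " ")
  if (anyDuplicated(pk)) stop("edge rules: duplicated pair entries")
  if (any(paste(singles$resname, singles$atom) %in%
          paste(amb$resname, amb$atom)))
    stop("edge rules: ambiguous and unambiguous singles overlap")
  tables <- list(pairs = pairs, singles = singles, ambiguous = amb)
  if (useCache) .edgeTablesCache$tables <- tables
  tables
}

#' Euclidean distance between two points
#'
#' `d(a, O) = sqrt((x_a - x_O)^2 + (y_a - y_O)^2 + (z_a - z_O)^2)`,
#' the distance used by the adjacent-atom disambiguation rule.
#'
#' @param a,o numeric length-3 coordinate vectors (Angstrom).
#' @return non-negative numeric distance.
#' @examples
#' euclideanDistance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclideanDistance <- function(a, o) {
  stopifnot(length(a) == 3, length(o) == 3, all(is.finite(c(a, o))))
  sqrt(sum((a - o)^2))
}

.newAssignment <- function(nucleotide, resname, intAtoms, moiety, edge,
                           method) {
  new("EdgeAssignment", nucleotide = nucleotide, resname = resname,
      intAtoms = sort(intAtoms), moiety = moiety, edge = edge,
      method = method)
}

#' Assign the moiety and nucleobase edge of a water-ribonucleotide contact
#'
#' Applies, in order: the ribose rule (`O2'` with `O3'` is ribose-sugar
#' mediated), the `O2'`-alone rule (SG-edge semantics on the ribose
#' moiety), the residue-aware two-atom pair lists, the unambiguous
#' single-atom table, and the adjacent-atom distance rule for ambiguous
#' single atoms (strictly nearer adjacent atom selects its edge; a tie
#' falls to the second-listed edge). Contacts touching only phosphate or
#' non-`O2'` ribose oxygens carry no edge. A water can bond at most two
#' atoms of one nucleobase; surplus atoms are trimmed to the two closest
#' to the water, with a warning. Two base atoms matching no pair-list
#' entry yield an `unclassified` assignment with a warning.
#'
#' @param structure an [RnpStructure-class] containing the nucleotide.
#' @param ntResid residue key of the ribonucleotide.
#' @param intAtoms character vector of the nucleotide's atoms
#'   hydrogen-bonded to the bridging water.
#' @param waterXYZ numeric length-3, water oxygen coordinates.
#' @param tables edge-rule tables from [edgePairTables()].
#' @return an [EdgeAssignment-class].
#' @examples
#' p <- generateEdgeProbe("rA", "N6", +0.8, tempfile(fileext = ".pdb"))
#' s <- readStructure(p$path)
#' w <- atoms(s)[atoms(s)$resclass == "WATER", ]
#' nt <- atoms(s)$resid[atoms(s)$resclass == "RIBONUCLEOTIDE"][1]
#' assignEdge(s, nt, "N6", c(w$x, w$y, w$z))
#' @export
assignEdge <- function(structure, ntResid, intAtoms, waterXYZ,
                       tables = edgePairTables()) {
  a <- atoms(structure)
  res <- a[a$resid == ntResid, , drop = FALSE]
  if (!nrow(res)) stop("residue not found: ", ntResid)
  resname <- sub("^r", "", res$resname[1])
  if (!resname %in% RIBONUCLEOTIDES)
    stop(ntResid, " is not a canonical ribonucleotide")
  intAtoms <- unique(canonicalAtomName(intAtoms))
  if (!length(intAtoms)) stop("intAtoms must be non-empty")
  unknown <- setdiff(intAtoms, res$atom)
  if (length(unknown))
    stop("atom(s) not present in ", ntResid, ": ",
         paste(unknown, collapse = ", "))
  moi <- moietyOf(resname, intAtoms)

  baseAtoms <- intAtoms[moi == "Nb"]
  hasO2p <- "O2'" %in% intAtoms
  hasO3p <- "O3'" %in% intAtoms
  if (length(baseAtoms) && any(moi == "Ph"))
    message("contact ", ntResid, " touches nucleobase and phosphate; ",
            "annotated by the nucleobase edge (Nb > Ph > Rb)")

  if (!length(baseAtoms)) {
    if (hasO2p && hasO3p)
      return(.newAssignment(ntResid, resname, intAtoms, "Rb", "NONE",
                            "ribose_rule"))
    if (hasO2p)
      return(.newAssignment(ntResid, resname, intAtoms, "Rb", "SG",
                            "unambiguous_single"))
    moiety <- if (any(moi == "Ph")) "Ph" else "Rb"
    return(.newAssignment(ntResid, resname, intAtoms, moiety, "NONE",
                          "moiety_rule"))
  }

  ## Nucleobase-mediated path; O2' may join a pair ([N3,O2'], [O2,O2']).
  eff <- c(baseAtoms, if (hasO2p) "O2'")
  if (length(eff) > 2) {
    d <- vapply(eff, function(at) {
      r <- res[res$atom == at, ]
      euclideanDistance(c(r$x, r$y, r$z), waterXYZ)
    }, numeric(1))
    keep <- names(sort(d))[1:2]
    warning("water bonds ", length(eff), " atoms of one nucleobase at ",
            ntResid, "; keeping the two closest (", paste(keep,
            collapse = ", "), ")")
    eff <- keep
  }

  if (length(eff) == 2) {
    s <- sort(eff)
    hit <- tables$pairs$resname == resname &
      ((tables$pairs$atom1 == s[1] & tables$pairs$atom2 == s[2]) |
       (tables$pairs$atom1 == s[2] & tables$pairs$atom2 == s[1]))
    if (any(hit))
      return(.newAssignment(ntResid, resname, intAtoms, "Nb",
                            tables$pairs$edge[which(hit)[1]], "pair_list"))
    warning("atom pair [", paste(s, collapse = ", "), "] of ", resname,
            " at ", ntResid, " matches no edge pair list; left ",
            "unclassified for manual review")
    return(.newAssignment(ntResid, resname, intAtoms, "Nb", "NONE",
                          "unclassified"))
  }

  atom <- eff
  hit <- tables$singles$resname == resname & tables$singles$atom == atom
  if (any(hit))
    return(.newAssignment(ntResid, resname, intAtoms, "Nb",
                          tables$singles$edge[which(hit)[1]],
                          "unambiguous_single"))
  hit <- tables$ambiguous$resname == resname & tables$ambiguous$atom == atom
  if (any(hit)) {
    rule <- tables$ambiguous[which(hit)[1], ]
    coord <- function(nm) {
      r <- res[res$atom == nm, ]
      if (!nrow(r))
        stop("adjacent atom ", nm, " missing from ", ntResid)
      c(r$x, r$y, r$z)
    }
    d1 <- euclideanDistance(coord(rule$adj1), waterXYZ)
    d2 <- euclideanDistance(coord(rule$adj2), waterXYZ)
    edge <- if (d1 < d2) rule$edge1 else rule$edge2
    return(.newAssignment(ntResid, resname, intAtoms, "Nb", edge,
                          "distance_rule"))
  }
  warning("single atom ", atom, " of ", resname, " at ", ntResid,
          " has no edge rule; left unclassified")
  .newAssignment(ntResid, resname, intAtoms, "Nb", "NONE", "unclassified")
}

#' Classify every water-nucleotide contact of a bridge
#'
#' Runs [assignEdge()] for each ribonucleotide member of a bridge using
#' the atoms it bonds to the bridging water.
#'
#' @param bridge a [WaterBridge-class].
#' @param structure the [RnpStructure-class] the bridge came from.
#' @param tables edge-rule tables.
#' @return named list of [EdgeAssignment-class], one per nt member.
#' @export
classifyBridgeContacts <- function(bridge, structure,
                                   tables = edgePairTables()) {
  a <- atoms(structure)
  wO <- a[a$resid == bridge@water & a$elem == "O", ][1, ]
  waterXYZ <- c(wO$x, wO$y, wO$z)
  inc <- .waterIncidence(bridge@waterBonds)
  out <- lapply(bridge@ntMembers, function(nt) {
    ia <- unique(inc$partner_atom[inc$partner == nt])
    assignEdge(structure, nt, ia, waterXYZ, tables)
  })
  stats::setNames(out, bridge@ntMembers)
}
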