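## Native geometric hydrogen-bond detection between water, amino-acid
## and ribonucleotide residues. The detector applies the three
## geometric criteria (D-A distance, H-A distance, D-H-A angle)
## natively so the package is self-contained; .hb2 ingestion (readHB2)
## reproduces an HBPLUS-based pipeline instead.

.BOND_COLS <- c("don_resid", "don_resname", "don_atom", "don_class",
                "acc_resid", "acc_resname", "acc_atom", "acc_class",
                "da", "ha", "dha", "kind")

.emptyBondTable <- function() {
  out <- data.frame(don_resid = character(0), don_resname = character(0),
                    don_atom = character(0), don_class = character(0),
                    acc_resid = character(0), acc_resname = character(0),
                    acc_atom = character(0), acc_class = character(0),
                    da = numeric(0), ha = numeric(0), dha = numeric(0),
                    kind = character(0), stringsAsFactors = FALSE)
  out
}

.bondKind <- function(class1, class2) {
  k <- rep("OTHER", length(class1))
  k[(class1 == "WATER" & class2 == "RIBONUCLEOTIDE") |
    (class2 == "WATER" & class1 == "RIBONUCLEOTIDE")] <- "WATER_RNA"
  k[(class1 == "WATER" & class2 == "AMINO_ACID") |
    (class2 == "WATER" & class1 == "AMINO_ACID")] <- "WATER_PROTEIN"
  k[(class1 == "AMINO_ACID" & class2 == "RIBONUCLEOTIDE") |
    (class2 == "AMINO_ACID" & class1 == "RIBONUCLEOTIDE")] <- "PROTEIN_RNA"
  k
}

## Polar-atom table of a structure: atoms with a donor/acceptor role.
.polarAtoms <- function(structure, waterNames = DEFAULT_WATER_NAMES) {
  a <- atoms(structure)
  a <- a[a$resclass %in% c("AMINO_ACID", "RIBONUCLEOTIDE", "WATER"), ,
         drop = FALSE]
  if (!nrow(a)) { a$role <- character(0); return(a) }
  role <- rep("none", nrow(a))
  isWat <- a$resclass == "WATER"
  role[isWat & a$elem == "O"] <- "both"
  for (rn in unique(a$resname[!isWat])) {
    tab <- donorAcceptorRoles(rn, waterNames)
    sel <- !isWat & a$resname == rn & a$atom %in% names(tab)
    role[sel] <- unname(tab[a$atom[sel]])
  }
  a$role <- role
  a[a$role != "none", , drop = FALSE]
}

## All candidate atom index pairs within `cutoff`, via a cell list.
.neighbourPairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- floor(xyz / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  byCell <- split(seq_len(n), key)
  keys <- names(byCell)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res <- vector("list", length(keys) * 14)
  k <- 0L
  for (ck in keys) {
    ia <- byCell[[ck]]
    cc <- cell[ia[1], ]
    for (r in seq_len(nrow(off))) {
      nk <- paste(cc[1] + off[r, 1], cc[2] + off[r, 2], cc[3] + off[r, 3])
      if (nk < ck) next                      # each unordered cell pair once
      ib <- byCell[[nk]]
      if (is.null(ib)) next
      k <- k + 1L
      if (nk == ck) {
        if (length(ia) < 2) { k <- k - 1L; next }
        res[[k]] <- t(utils::combn(ia, 2))
      } else {
        res[[k]] <- cbind(rep(ia, each = length(ib)), rep(ib, length(ia)))
      }
    }
  }
  pr <- do.call(rbind, res[seq_len(k)])
  if (is.null(pr)) return(matrix(integer(0), ncol = 2))
  d2 <- rowSums((xyz[pr[, 1], , drop = FALSE] -
                 xyz[pr[, 2], , drop = FALSE])^2)
  pr[d2 <= cutoff^2, , drop = FALSE]
}

## Idealized hydrogen positions for a fixed-geometry donor atom.
## Returns a 0..2 x 3 matrix. Rotatable donors return zero rows.
.inferH <- function(resAtoms, resname, resclass, donorAtom) {
  D <- unlist(resAtoms[resAtoms$atom == donorAtom, c("x", "y", "z")])
  getXYZ <- function(nm) {
    r <- resAtoms[resAtoms$atom == nm, c("x", "y", "z")]
    if (nrow(r)) unlist(r[1, ]) else NULL
  }
  unitv <- function(v) v / sqrt(sum(v^2))
  nb <- atomNeighbours(resname, donorAtom)
  have <- Filter(Negate(is.null), lapply(nb, getXYZ))
  if (length(have) >= 2) {
    ## ring NH / secondary amine: H opposite the bisector of the two
    ## heavy neighbours, N-H 1.00 A.
    d <- unitv(unitv(D - have[[1]]) + unitv(D - have[[2]]))
    return(matrix(D + 1.00 * d, ncol = 3))
  }
  if (length(have) == 1) {
    ## sp2 amine (-NH2) or amide NH: two in-plane hydrogens at 120 deg
    ## from the N-C bond; the plane is fixed by a reference atom bonded
    ## to the same carbon.
    C <- have[[1]]
    refNames <- switch(paste(resname, donorAtom),
      "A N6" = c("N1", "C5"), "G N2" = c("N1", "N3"),
      "C N4" = c("N3", "C5"),
      "ASN ND2" = c("OD1", "CB"), "GLN NE2" = c("OE1", "CG"),
      "ARG NH1" = c("NE", "NH2"), "ARG NH2" = c("NE", "NH1"),
      "U N3" = c("C2", "C4"), "G N1" = c("C2", "C6"),
      character(0))
    ref <- NULL
    for (rn in refNames) { ref <- getXYZ(rn); if (!is.null(ref)) break }
    if (is.null(ref)) return(matrix(numeric(0), ncol = 3))
    u <- unitv(D - C)
    w <- ref - C
    perp <- w - sum(w * u) * u
    if (sqrt(sum(perp^2)) < 1e-6) return(matrix(numeric(0), ncol = 3))
    perp <- unitv(perp)
    d1 <- u * cos(pi / 3) - perp * sin(pi / 3)
    d2 <- u * cos(pi / 3) + perp * sin(pi / 3)
    return(rbind(D + 1.00 * d1, D + 1.00 * d2))
  }
  matrix(numeric(0), ncol = 3)
}

## Backbone amide N: treat the previous residue's C as second neighbour
## when present so the H position is determined.
.backboneNH <- function(allAtoms, row) {
  D <- c(row$x, row$y, row$z)
  ca <- allAtoms[allAtoms$resid == row$resid & allAtoms$atom == "CA", ]
  pc <- allAtoms[allAtoms$chain == row$chain &
                 allAtoms$resno == row$resno - 1L & allAtoms$atom == "C", ]
  if (!nrow(ca) || !nrow(pc)) return(matrix(numeric(0), ncol = 3))
  unitv <- function(v) v / sqrt(sum(v^2))
  d <- unitv(unitv(D - unlist(ca[1, c("x", "y", "z")])) +
             unitv(D - unlist(pc[1, c("x", "y", "z")])))
  matrix(D + 1.00 * d, ncol = 3)
}

#' Detect hydrogen bonds in a structure
#'
#' Enumerates donor-acceptor contacts among water, amino-acid and
#' ribonucleotide residues that satisfy the geometric criteria. In
#' `heavy_atom` mode (default) only the donor-acceptor distance is
#' enforced; in `with_hydrogens` mode donors with fixed hydrogen
#' geometry (amides, ring NH, guanidinium, nucleobase amines) get
#' idealized hydrogens (N-H 1.00 Angstrom) and the full three-criterion
#' test, while rotatable donors (water, hydroxyls, Lys NZ, O2') remain
#' distance-only because their hydrogen position is underdetermined.
#' Water-water contacts are not enumerated; each unordered atom pair is
#' reported once.
#'
#' @param structure an [RnpStructure-class].
#' @param criteria an [HBondCriteria-class].
#' @param mode `"heavy_atom"` or `"with_hydrogens"`.
#' @param waterNames residue names treated as water.
#' @return data.frame with one row per hydrogen bond: donor and acceptor
#'   residue/atom columns, `da`, `ha`, `dha` (NA when not evaluated) and
#'   `kind` (`WATER_RNA`, `WATER_PROTEIN`, `PROTEIN_RNA`, `OTHER`).
#' @examples
#' mf <- fixtureManifest(list(bridgeSpec("A1:w:N1")), seed = 7)
#' fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
#' s <- readStructure(fx$path)
#' detectHBonds(s, hbondCriteria())
#' @export
detectHBonds <- function(structure, criteria = hbondCriteria(),
                         mode = c("heavy_atom", "with_hydrogens"),
                         waterNames = DEFAULT_WATER_NAMES) {
  mode <- match.arg(mode)
  validObject(criteria)
  pol <- .polarAtoms(structure, waterNames)
  if (nrow(pol) < 2) return(.emptyBondTable())
  xyz <- as.matrix(pol[, c("x", "y", "z")])
  pr <- .neighbourPairs(xyz, criteria@maxDA)
  if (!nrow(pr)) return(.emptyBondTable())

  i <- pr[, 1]; j <- pr[, 2]
  keep <- pol$resid[i] != pol$resid[j] &
    !(pol$resclass[i] == "WATER" & pol$resclass[j] == "WATER")
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(.emptyBondTable())

  canDonate <- function(r) r %in% c("donor", "both")
  canAccept <- function(r) r %in% c("acceptor", "both")
  dir_ij <- canDonate(pol$role[i]) & canAccept(pol$role[j])
  dir_ji <- canDonate(pol$role[j]) & canAccept(pol$role[i])
  keep <- dir_ij | dir_ji
  i <- i[keep]; j <- j[keep]
  dir_ij <- dir_ij[keep]; dir_ji <- dir_ji[keep]
  if (!length(i)) return(.emptyBondTable())
  da <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))

  allAtoms <- atoms(structure)
  evalDirection <- function(d, a) {
    ## Returns c(ok, ha, dha) for donor index d, acceptor index a.
    if (mode == "heavy_atom" ||
        isRotatableDonor(pol$resclass[d], pol$atom[d]))
      return(c(1, NA, NA))
    row <- pol[d, ]
    H <- if (row$resclass == "AMINO_ACID" && row$atom == "N")
      .backboneNH(allAtoms, row)
    else .inferH(allAtoms[allAtoms$resid == row$resid, , drop = FALSE],
                 row$resname, row$resclass, row$atom)
    if (!nrow(H)) return(c(1, NA, NA))       # geometry underdetermined
    A <- xyz[a, ]; D <- xyz[d, ]
    best <- c(0, NA, NA)
    for (r in seq_len(nrow(H))) {
      h <- H[r, ]
      ha <- sqrt(sum((A - h)^2))
      v1 <- D - h; v2 <- A - h
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ha <= row_maxHA && ang >= row_minDHA &&
          (is.na(best[2]) || ha < best[2]))
        best <- c(1, ha, ang)
    }
    best
  }
  row_maxHA <- criteria@maxHA
  row_minDHA <- criteria@minDHA

  n <- length(i)
  ok <- logical(n); ha <- rep(NA_real_, n); dha <- rep(NA_real_, n)
  don <- integer(n); acc <- integer(n)
  for (k in seq_len(n)) {
    res_ij <- if (dir_ij[k]) evalDirection(i[k], j[k]) else c(0, NA, NA)
    res_ji <- if (dir_ji[k]) evalDirection(j[k], i[k]) else c(0, NA, NA)
    if (res_ij[1] > 0) {
      ok[k] <- TRUE; don[k] <- i[k]; acc[k] <- j[k]
      ha[k] <- res_ij[2]; dha[k] <- res_ij[3]
    } else if (res_ji[1] > 0) {
      ok[k] <- TRUE; don[k] <- j[k]; acc[k] <- i[k]
      ha[k] <- res_ji[2]; dha[k] <- res_ji[3]
    }
  }
  if (!any(ok)) return(.emptyBondTable())
  don <- don[ok]; acc <- acc[ok]
  out <- data.frame(
    don_resid = pol$resid[don], don_resname = pol$resname[don],
    don_atom = pol$atom[don], don_class = pol$resclass[don],
    acc_resid = pol$resid[acc], acc_resname = pol$resname[acc],
    acc_atom = pol$atom[acc], acc_class = pol$resclass[acc],
    da = da[ok], ha = ha[ok], dha = dha[ok],
    kind = .bondKind(pol$resclass[don], pol$resclass[acc]),
    stringsAsFactors = FALSE)
  ## one row per unordered atom pair, deterministic order
  pairKey <- apply(cbind(paste(out$don_resid, out$don_atom),
                         paste(out$acc_resid, out$acc_atom)), 1,
                   function(r) paste(sort(r), collapse = " | "))
  out <- out[!duplicated(pairKey), , drop = FALSE]
  out <- out[order(out$don_resid, out$don_atom, out$acc_resid,
                   out$acc_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}
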