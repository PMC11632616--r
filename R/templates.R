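## Idealized heavy-atom residue templates used by the synthetic-fixture
## generator. Geometry is idealized (regular-polygon rings, standard-ish
## bond lengths): the pipeline never inspects covalent geometry, only
## inter-residue hydrogen-bond distances/angles, and the generator
## validates every placement against the detection criteria with
## explicit margins. Nucleobases are planar (local z = 0), which keeps
## the edge-sector geometry exact: each exocyclic ambiguous atom sits on
## the symmetry axis of its two adjacent ring atoms.

.hexagon <- function(names, angles, r = 1.38) {
  a <- angles * pi / 180
  m <- cbind(x = r * cos(a), y = r * sin(a), z = 0)
  rownames(m) <- names
  m
}

## Purine scaffold: six-ring N1 C2 N3 C4 C5 C6 with the five-ring
## (C4 C5 N7 C8 N9) fused on the C4-C5 edge, exocyclic substituents on
## the radial direction at ring distance + 1.35 A.
.purineBase <- function(resname) {
  ring <- .hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"),
                   c(0, -60, -120, 180, 120, 60))
  exo <- function(at, angle)
    matrix(c(2.73 * cos(angle * pi / 180),
             2.73 * sin(angle * pi / 180), 0), nrow = 1,
           dimnames = list(at, c("x", "y", "z")))
  ## fused pentagon on C4-C5
  C4 <- ring["C4", ]; C5 <- ring["C5", ]
  mid <- (C4 + C5) / 2
  u <- mid / sqrt(sum(mid^2))
  s <- sqrt(sum((C4 - C5)^2))
  R5 <- s / (2 * sin(pi / 5))
  ctr <- mid + u * R5 * cos(pi / 5)
  th4 <- atan2(C4[2] - ctr[2], C4[1] - ctr[1])
  th5 <- atan2(C5[2] - ctr[2], C5[1] - ctr[1])
  ## walk the pentagon from C5 away from C4
  d <- th5 - th4
  d <- atan2(sin(d), cos(d))
  step <- if (d > 0) 2 * pi / 5 else -2 * pi / 5
  penta <- function(k)
    c(ctr[1] + R5 * cos(th5 + k * step),
      ctr[2] + R5 * sin(th5 + k * step), 0)
  five <- rbind(N7 = penta(1), C8 = penta(2), N9 = penta(3))
  colnames(five) <- c("x", "y", "z")
  base <- rbind(ring, five)
  if (resname == "A") {
    base <- rbind(base, exo("N6", 60))
  } else {
    base <- rbind(base, exo("O6", 60), exo("N2", -60))
  }
  base
}

.pyrimidineBase <- function(resname) {
  ring <- .hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"),
                   c(180, -120, -60, 0, 60, 120))
  exo <- function(at, angle) {
    m <- matrix(c(2.73 * cos(angle * pi / 180),
                  2.73 * sin(angle * pi / 180), 0), nrow = 1,
                dimnames = list(at, c("x", "y", "z")))
    m
  }
  rbind(ring, exo("O2", -120),
        if (resname == "C") exo("N4", 0) else exo("O4", 0))
}

## Ribose + phosphate in a local frame: C1' at origin, +x pointing away
## from the base; O2'/O3' ~2.9 A apart so that a water can bond both
## (the ribose-sugar rule). The sign of the local y axis is chosen per
## base so that O2' lies on the sugar-edge side.
.SUGAR_LOCAL <- rbind(
  "C1'" = c(0.0, 0.0, 0.0),
  "O4'" = c(0.7, 1.2, 0.4),
  "C4'" = c(2.1, 1.3, 0.2),
  "C3'" = c(2.5, -0.1, -0.3),
  "C2'" = c(1.2, -1.0, -0.4),
  "O2'" = c(1.3, -2.2, 0.4),
  "O3'" = c(3.7, -0.6, 0.3),
  "C5'" = c(3.0, 2.5, 0.5),
  "O5'" = c(2.6, 3.2, 1.6),
  "P"   = c(3.3, 4.6, 1.9),
  "OP1" = c(4.7, 4.4, 2.2),
  "OP2" = c(2.6, 5.3, 3.0))

.ntTemplate <- function(resname) {
  resname <- sub("^r", "", toupper(resname))
  stopifnot(resname %in% RIBONUCLEOTIDES)
  isPur <- resname %in% c("A", "G")
  base <- if (isPur) .purineBase(resname) else .pyrimidineBase(resname)
  glyN <- if (isPur) "N9" else "N1"
  Ng <- base[glyN, ]
  if (isPur) {
    nb <- atomNeighbours(resname, glyN)
    anchor <- colMeans(base[nb, , drop = FALSE])
    u <- (Ng - anchor); u <- u / sqrt(sum(u^2))
  } else {
    u <- Ng / sqrt(sum(Ng^2))
  }
  C1p <- Ng + 1.47 * u
  th <- atan2(u[2], u[1])
  ## flip the sugar's local y so O2' lands on the N3 (purine) / O2
  ## (pyrimidine) side of the glycosidic bond, keeping the sugar edge
  ## geometrically coherent.
  sgRef <- if (isPur) base["N3", ] else base["O2", ]
  place <- function(flip) {
    loc <- .SUGAR_LOCAL
    if (flip) loc[, 2] <- -loc[, 2]
    rot <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0),
                 c(0, 0, 1))
    sweep(loc %*% t(rot), 2, C1p, `+`)
  }
  s1 <- place(FALSE); s2 <- place(TRUE)
  d1 <- sqrt(sum((s1["O2'", ] - sgRef)^2))
  d2 <- sqrt(sum((s2["O2'", ] - sgRef)^2))
  sugar <- if (d1 <= d2) s1 else s2
  colnames(sugar) <- c("x", "y", "z")
  rbind(base, sugar)
}

.AA_BACKBONE <- rbind(
  N = c(0.00, 0.00, 0.00),
  CA = c(1.46, 0.00, 0.00),
  C = c(2.10, 1.35, 0.00),
  O = c(3.33, 1.42, 0.00))

.AA_SIDE <- list(
  ALA = rbind(CB = c(1.95, -0.80, 1.20)),
  GLY = NULL,
  SER = rbind(CB = c(1.95, -0.80, 1.20), OG = c(2.00, -2.20, 1.30)),
  THR = rbind(CB = c(1.95, -0.80, 1.20), OG1 = c(2.00, -2.20, 1.30),
              CG2 = c(0.90, -1.20, 2.30)),
  CYS = rbind(CB = c(1.95, -0.80, 1.20), SG = c(2.15, -2.45, 1.50)),
  VAL = rbind(CB = c(1.95, -0.80, 1.20), CG1 = c(0.90, -1.20, 2.30),
              CG2 = c(2.90, -1.40, 0.60)),
  LEU = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.30, 2.30),
              CD1 = c(2.00, -2.40, 2.50), CD2 = c(0.20, -1.70, 3.50)),
  ILE = rbind(CB = c(1.95, -0.80, 1.20), CG1 = c(1.00, -1.30, 2.30),
              CG2 = c(2.90, -1.40, 0.60), CD1 = c(1.60, -2.60, 2.60)),
  PRO = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.00, 2.20),
              CD = c(-0.30, -0.90, 1.40)),
  PHE = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.60, -2.10, 1.50),
              CD1 = c(2.85, -2.50, 1.60), CD2 = c(0.80, -3.10, 1.70),
              CE1 = c(3.40, -3.70, 1.90), CE2 = c(1.30, -4.30, 2.00),
              CZ = c(2.60, -4.60, 2.10)),
  TYR = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.60, -2.10, 1.50),
              CD1 = c(2.85, -2.50, 1.60), CD2 = c(0.80, -3.10, 1.70),
              CE1 = c(3.40, -3.70, 1.90), CE2 = c(1.30, -4.30, 2.00),
              CZ = c(2.60, -4.60, 2.10), OH = c(3.20, -5.80, 2.40)),
  TRP = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.60, -2.10, 1.50),
              CD1 = c(2.90, -2.40, 1.60), NE1 = c(3.10, -3.75, 1.70),
              CD2 = c(0.90, -3.30, 1.60), CE2 = c(1.85, -4.40, 1.70)),
  ASP = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.60, -2.10, 1.50),
              OD1 = c(2.30, -3.10, 1.70), OD2 = c(0.35, -2.20, 1.60)),
  ASN = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.60, -2.10, 1.50),
              OD1 = c(2.30, -3.10, 1.70), ND2 = c(0.35, -2.20, 1.60)),
  GLU = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.30, 2.30),
              CD = c(1.60, -2.60, 2.60), OE1 = c(2.85, -2.90, 2.70),
              OE2 = c(0.70, -3.50, 2.80)),
  GLN = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.30, 2.30),
              CD = c(1.60, -2.60, 2.60), OE1 = c(2.85, -2.90, 2.70),
              NE2 = c(0.70, -3.50, 2.80)),
  LYS = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.30, 2.30),
              CD = c(1.60, -2.60, 2.60), CE = c(0.70, -3.80, 2.90),
              NZ = c(1.40, -5.00, 3.20)),
  ARG = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.30, 2.30),
              CD = c(1.60, -2.60, 2.60), NE = c(0.70, -3.70, 2.90),
              CZ = c(1.10, -5.00, 3.10), NH1 = c(2.40, -5.30, 3.10),
              NH2 = c(0.15, -5.90, 3.30)),
  HIS = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.60, -2.10, 1.50),
              ND1 = c(2.90, -2.50, 1.50), CD2 = c(0.75, -3.20, 1.70),
              CE1 = c(3.00, -3.85, 1.70), NE2 = c(1.70, -4.25, 1.80)),
  MET = rbind(CB = c(1.95, -0.80, 1.20), CG = c(1.00, -1.30, 2.30),
              SD = c(1.70, -2.85, 2.70), CE = c(0.60, -4.10, 2.90))
)

.aaTemplate <- function(resname) {
  resname <- toupper(resname)
  stopifnot(resname %in% AMINO_ACIDS_3L)
  m <- rbind(.AA_BACKBONE, .AA_SIDE[[resname]])
  colnames(m) <- c("x", "y", "z")
  m
}

#' Idealized residue template
#'
#' Heavy-atom coordinate template (Angstrom, local frame) for one of
#' the 20 canonical amino acids, the 4 canonical ribonucleotides
#' (`"rA"`/`"A"`, ...) or water, as used by the fixture generator.
#'
#' @param resname residue name.
#' @return matrix with atom-name rownames and `x`, `y`, `z` columns.
#' @examples
#' residueTemplate("SER")
#' head(residueTemplate("rG"))
#' @export
residueTemplate <- function(resname) {
  rn <- toupper(trimws(resname))
  if (rn %in% DEFAULT_WATER_NAMES)
    return(matrix(c(0, 0, 0), nrow = 1,
                  dimnames = list("O", c("x", "y", "z"))))
  if (sub("^R", "", rn) %in% RIBONUCLEOTIDES && nchar(rn) <= 2)
    return(.ntTemplate(sub("^R", "", rn)))
  .aaTemplate(rn)
}
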