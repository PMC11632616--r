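test_that("role tables give expected donor/acceptor assignments", {
  expect_equal(donorAcceptorRoles("HOH"), c(O = "both"))
  r <- donorAcceptorRoles("A")
  expect_equal(r[["N7"]], "acceptor")
  expect_equal(r[["N6"]], "donor")
  expect_equal(donorAcceptorRoles("ARG")[["NH2"]], "donor")
  expect_equal(donorAcceptorRoles("HIS")[["ND1"]], "both")
  expect_false("N" %in% names(donorAcceptorRoles("PRO")))
})

test_that("distance criterion admits 2.8 A and rejects 3.40 A contacts", {
  tp <- residueTemplate("G")
  O6 <- tp["O6", ]; C6 <- tp["C6", ]
  u <- (O6 - C6) / sqrt(sum((O6 - C6)^2))
  s1 <- residuePlusWater("G", O6 + 2.8 * u)
  b1 <- detectHBonds(s1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$kind, "WATER_RNA")
  expect_equal(sort(c(b1$don_atom, b1$acc_atom)), c("O", "O6"))

  tpS <- residueTemplate("SER")
  OG <- tpS["OG", ]; CB <- tpS["CB", ]
  v <- (OG - CB) / sqrt(sum((OG - CB)^2))
  s2 <- residuePlusWater("SER", OG + 3.40 * v)
  expect_equal(nrow(detectHBonds(s2)), 0)
})

test_that("with_hydrogens rejects donors pointing away from the acceptor", {
  tp <- residueTemplate("ASN")
  ND2 <- tp["ND2", ]; CG <- tp["CG", ]; OD1 <- tp["OD1", ]
  u <- (ND2 - CG) / sqrt(sum((ND2 - CG)^2))
  behind <- ND2 - 3.0 * u     # opposite the amine hydrogens

  ## trigonometric oracle: both idealized sp2 N-H directions lie at 60
  ## degrees from u in the amide plane; for an acceptor along -u the
  ## D-H-A angle is then well below the 90-degree cutoff
  w <- OD1 - CG
  perp <- w - sum(w * u) * u; perp <- perp / sqrt(sum(perp^2))
  for (sgn in c(-1, 1)) {
    h <- ND2 + 1.0 * (u * cos(pi / 3) + sgn * perp * sin(pi / 3))
    v1 <- ND2 - h; v2 <- behind - h
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_lt(ang, 90)
  }

  s <- residuePlusWater("ASN", behind)
  heavy <- detectHBonds(s, mode = "heavy_atom")
  strict <- detectHBonds(s, mode = "with_hydrogens")
  hasND2 <- function(b) any(b$don_atom == "ND2" | b$acc_atom == "ND2")
  expect_true(hasND2(heavy))
  expect_false(hasND2(strict))

  ## and in front of the hydrogens the bond survives strict mode
  front <- residuePlusWater("ASN", ND2 + 3.0 * u)
  expect_true(hasND2(detectHBonds(front, mode = "with_hydrogens")))
})

test_that("detection equals the brute-force all-pairs oracle", {
  specs <- list(
    list(bridgeSpec("A1:w:N1")),
    list(bridgeSpec("A1:w:N1", cyclic = TRUE)),
    list(bridgeSpec("A1:w:N1",
                    aa = list(list(res = "THR", portion = "ms")),
                    nt = list(list(res = "G", annotation = "Rb")))))
  for (k in seq_along(specs)) {
    mf <- fixtureManifest(specs[[k]], seed = 100 + k, decoyWaters = 1L,
                          decoyBonds = 1L)
    fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
    s <- readStructure(fx$path)
    expect_lte(nrow(atoms(s)), 80)
    expect_equal(bondKeys(detectHBonds(s)), bruteForceHBonds(s),
                 info = paste("fixture", k))
  }
  ## and on the single-residue probes (well under 50 atoms)
  p <- generateEdgeProbe("rG", "O6", 0.7, tempfile(fileext = ".pdb"))
  s <- readStructure(p$path)
  expect_lte(nrow(atoms(s)), 50)
  expect_equal(bondKeys(detectHBonds(s)), bruteForceHBonds(s))
})

test_that("loosening criteria never removes a detected bond", {
  ens <- ensembleFixture()
  base <- bondKeys(detectHBonds(ens$structure, hbondCriteria()))
  loose <- bondKeys(detectHBonds(ens$structure,
                                 hbondCriteria(maxDA = 3.8)))
  expect_true(all(base %in% loose))

  ## a bent contact at the single, fixed Trp NE1-H: H-A distance within
  ## the cutoff but D-H-A = 60 degrees, so only the relaxed angle
  ## criterion admits the bond (geometry constructed trigonometrically)
  tp <- residueTemplate("TRP")
  NE1 <- tp["NE1", ]; CD1 <- tp["CD1", ]; CE2 <- tp["CE2", ]
  unitv <- function(v) v / sqrt(sum(v^2))
  hd <- unitv(unitv(NE1 - CD1) + unitv(NE1 - CE2))
  h <- NE1 + 1.0 * hd
  pp <- unitv(CD1 - NE1 - sum((CD1 - NE1) * hd) * hd)
  acc <- h + 2.3 * (cos(2 * pi / 3) * hd + sin(2 * pi / 3) * pp)
  v1 <- NE1 - h; v2 <- acc - h
  dha <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(dha, 60, tolerance = 1e-6)     # below the 90-degree cutoff
  expect_lt(sqrt(sum((acc - h)^2)), 2.7)      # H-A admissible
  expect_lt(sqrt(sum((acc - NE1)^2)), 3.35)   # D-A admissible

  s <- residuePlusWater("TRP", acc)
  strict <- bondKeys(detectHBonds(s, hbondCriteria(), "with_hydrogens"))
  relaxed <- bondKeys(detectHBonds(s, hbondCriteria(minDHA = 10),
                                   "with_hydrogens"))
  expect_true(all(strict %in% relaxed))
  expect_gt(length(relaxed), length(strict))
  heavy <- bondKeys(detectHBonds(s, hbondCriteria(), "heavy_atom"))
  expect_equal(relaxed, heavy)
})

test_that("detection is invariant under atom enumeration order", {
  mf <- fixtureManifest(list(bridgeSpec("A2:w:N1")), seed = 9)
  fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
  a <- atoms(fx$structure)
  set.seed(1)
  sh <- a[sample(nrow(a)), ]
  s2 <- structureFromAtoms(chain = sh$chain, resno = sh$resno,
                           resname = sh$resname, atom = sh$atom,
                           x = sh$x, y = sh$y, z = sh$z, b = sh$b)
  expect_equal(bondKeys(detectHBonds(fx$structure)),
               bondKeys(detectHBonds(s2)))
})
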