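test_that("fixture generation is reproducible for a given seed", {
  mf1 <- fixtureManifest(list(bridgeSpec("A1:w:N1"),
                              bridgeSpec("A2:w:N1", cyclic = TRUE)),
                         seed = 31)
  mf2 <- fixtureManifest(list(bridgeSpec("A1:w:N1"),
                              bridgeSpec("A2:w:N1", cyclic = TRUE)),
                         seed = 31)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  generateFixture(mf1, f1)
  generateFixture(mf2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## a different seed changes the B-factors but not the topologies
  mf3 <- fixtureManifest(list(bridgeSpec("A1:w:N1"),
                              bridgeSpec("A2:w:N1", cyclic = TRUE)),
                         seed = 32)
  expect_false(identical(mf1$entries[[1]]$waterB,
                         mf3$entries[[1]]$waterB))
})

test_that("infeasible requests fail before writing", {
  expect_error(bridgeSpec("A4:w:N3"), "infeasible")
  expect_error(bridgeSpec("A1:w:N1",
                          nt = list(list(res = "C", annotation = "HG"))),
               "pyrimidines")
  expect_error(bridgeSpec("A1:w:N1",
                          aa = list(list(res = "GLY", portion = "s"))),
               "side-chain")
  expect_error(generateEdgeProbe("rA", "N1", 0.5, tempfile()),
               "ambiguous")
})

test_that("decoy waters and within-class bonds never become bridges", {
  mf <- fixtureManifest(list(bridgeSpec("A1:w:N1")), seed = 8,
                        decoyWaters = 5L, decoyBonds = 2L)
  fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
  s <- readStructure(fx$path)
  set <- surveyStructure(s)
  expect_length(set, 1)
  expect_equal(length(set@waterB), 6)   # 1 bridging + 5 decoys
  ## the within-class decoy bonds are detected but classified OTHER
  b <- set@hbonds
  expect_true(any(b$kind == "OTHER"))
  expect_false(any(b$kind == "PROTEIN_RNA"))
})

test_that("intended contacts carry the stated geometric margins", {
  ens <- ensembleFixture()
  b <- ens$set@hbonds
  wb <- b[b$kind %in% c("WATER_RNA", "WATER_PROTEIN"), ]
  expect_true(all(wb$da <= 3.35 - 0.2 + 1e-3))
  ## nothing sits in the guard band just above the cutoff
  loose <- detectHBonds(ens$structure, hbondCriteria(maxDA = 3.55))
  expect_equal(nrow(loose), nrow(b))
})

test_that("the default ensemble covers the advertised cases", {
  ens <- ensembleFixture()
  fx <- ens$fx
  expect_gte(nrow(fx$bridges), 40)
  topos <- unique(fx$bridges$label)
  for (t in c("A1:w:N1", "A2:w:N1", "A1:w:N2", "A3:w:N1", "A2:w:N2",
              "A1:w:N3"))
    expect_true(all(c(t, paste0("cyc-", t)) %in% topos), info = t)
  expect_true(any(fx$bridges$overTetrahedral))
  expect_true(any(grepl("\\(ms\\)", fx$bridges$name)))
  expect_true(any(fx$ntEdges$moiety == "Rb" & fx$ntEdges$edge == "NONE"))
  expect_true(any(fx$ntEdges$moiety == "Ph"))
  expect_true(all(c("WC", "HG", "SG") %in% fx$ntEdges$edge))
})

test_that("edge probes place the water on the requested side", {
  for (disp in c(-0.6, 0.6)) {
    p <- generateEdgeProbe("rG", "N2", disp, tempfile(fileext = ".pdb"))
    s <- readStructure(p$path)
    a <- atoms(s)
    w <- unlist(a[a$resclass == "WATER", c("x", "y", "z")])
    coord <- function(at) unlist(a[a$atom == at &
                                     a$resclass == "RIBONUCLEOTIDE",
                                   c("x", "y", "z")])
    d1 <- euclideanDistance(coord("N1"), w)   # first-listed adjacent
    d2 <- euclideanDistance(coord("N3"), w)
    if (disp > 0) expect_lt(d1, d2) else expect_gt(d1, d2)
    expect_equal(euclideanDistance(coord("N2"), w), 2.8,
                 tolerance = 1e-3)
  }
})
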