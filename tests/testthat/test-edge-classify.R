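test_that("euclidean distance matches closed forms", {
  expect_equal(euclideanDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclideanDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclideanDistance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
})

test_that("edge rule tables load and are internally consistent", {
  tb <- edgePairTables()
  expect_setequal(names(tb), c("pairs", "singles", "ambiguous"))
  expect_true(all(tb$pairs$edge %in% c("WC", "HG", "SG")))
  ## pair entries only cite atoms of the residue's chemical graph
  for (i in seq_len(nrow(tb$pairs))) {
    tp <- rownames(residueTemplate(tb$pairs$resname[i]))
    expect_true(all(c(tb$pairs$atom1[i], tb$pairs$atom2[i]) %in% tp))
  }
  ## no atom is both unambiguous and ambiguous
  expect_length(intersect(paste(tb$singles$resname, tb$singles$atom),
                          paste(tb$ambiguous$resname, tb$ambiguous$atom)),
                0)
})

mkNtWater <- function(res, waterXYZ) {
  s <- residuePlusWater(res, waterXYZ, chain = "B", resno = 7L)
  list(s = s, nt = sprintf("B/7/%s", sub("^r", "", toupper(res))),
       w = waterXYZ)
}

test_that("two-atom contacts resolve through the pair lists", {
  tp <- residueTemplate("G")
  mid <- (tp["N1", ] + tp["O6", ]) / 2 + c(0, 0, 2.2)
  x <- mkNtWater("G", mid)
  a <- assignEdge(x$s, x$nt, c("N1", "O6"), x$w)
  expect_equal(a@edge, "WC")
  expect_equal(a@method, "pair_list")
  expect_equal(a@moiety, "Nb")

  tpU <- residueTemplate("U")
  y <- mkNtWater("U", (tpU["N1", ] + tpU["O2", ]) / 2 + c(0, 0, 2.2))
  expect_equal(assignEdge(y$s, y$nt, c("N1", "O2"), y$w)@edge, "SG")

  ## an unlisted base-atom pair is left unclassified with a warning
  z <- mkNtWater("A", (tp["N1", ] + tp["N7", ]) / 2 + c(0, 0, 2.2))
  expect_warning(u <- assignEdge(z$s, z$nt, c("N1", "N7"), z$w),
                 "no edge pair list")
  expect_equal(u@edge, "NONE")
  expect_equal(u@method, "unclassified")
})

test_that("single atoms use unambiguous table, O2' and ribose rules", {
  tp <- residueTemplate("G")
  x <- mkNtWater("G", tp["N7", ] + c(0, 0, 2.8))
  a <- assignEdge(x$s, x$nt, "N7", x$w)
  expect_equal(a@edge, "HG")
  expect_equal(a@method, "unambiguous_single")

  tpU <- residueTemplate("U")
  y <- mkNtWater("U", tpU["O2'", ] + c(0, 0, 2.8))
  a2 <- assignEdge(y$s, y$nt, "O2'", y$w)
  expect_equal(a2@edge, "SG")          # O2' alone carries SG semantics
  expect_equal(a2@moiety, "Rb")

  a3 <- assignEdge(y$s, y$nt, c("O2'", "O3'"), y$w)
  expect_equal(a3@method, "ribose_rule")  # with O3' it is ribose-mediated
  expect_equal(a3@moiety, "Rb")
  expect_equal(a3@edge, "NONE")

  a4 <- assignEdge(y$s, y$nt, "OP1", y$w)
  expect_equal(a4@moiety, "Ph")
  expect_equal(a4@edge, "NONE")
})

test_that("the distance rule follows the nearer adjacent atom strictly", {
  for (probe in list(c("rA", "N6"), c("rG", "O6"), c("rG", "N2"),
                     c("rC", "O2"), c("rU", "O2"))) {
    for (disp in c(-0.8, 0.8)) {
      p <- generateEdgeProbe(probe[1], probe[2], disp,
                             tempfile(fileext = ".pdb"))
      s <- readStructure(p$path)
      w <- atoms(s)[atoms(s)$resclass == "WATER", ]
      a <- assignEdge(s, p$nt, p$intAtom, c(w$x, w$y, w$z))
      expect_equal(a@edge, p$expectedEdge,
                   info = paste(probe[1], probe[2], disp))
      expect_equal(a@method, "distance_rule")
    }
  }
})

test_that("an exact distance tie falls to the second-listed edge", {
  ## integer-coordinate construction: d(N1, O) == d(C5, O) exactly
  s <- structureFromAtoms(
    chain = c("B", "B", "B", "W"), resno = c(1, 1, 1, 2),
    resname = c("A", "A", "A", "HOH"), atom = c("N6", "N1", "C5", "O"),
    x = c(0, 1, -1, 0), y = c(0, 1, 1, -2.8), z = c(0, 0, 0, 0))
  a <- assignEdge(s, "B/1/A", "N6", c(0, -2.8, 0))
  expect_equal(a@edge, "HG")   # WC requires strictly smaller d(N1, O)
})

test_that("the assigned edge flips exactly once across the bisector", {
  disps <- seq(-1.2, 1.2, by = 0.2)
  edges <- vapply(disps, function(d) {
    p <- generateEdgeProbe("rA", "N6", d, tempfile(fileext = ".pdb"))
    s <- readStructure(p$path)
    w <- atoms(s)[atoms(s)$resclass == "WATER", ]
    assignEdge(s, p$nt, "N6", c(w$x, w$y, w$z))@edge
  }, character(1))
  expect_equal(sum(edges[-1] != edges[-length(edges)]), 1)
  expect_equal(edges[1], "HG")                  # toward C5
  expect_equal(edges[length(edges)], "WC")      # toward N1
})

test_that("more than two base atoms are trimmed to the two closest", {
  tp <- residueTemplate("G")
  mid <- (tp["N1", ] + tp["O6", ]) / 2 + c(0, 0, 2.0)
  x <- mkNtWater("G", mid)
  expect_warning(a <- assignEdge(x$s, x$nt, c("N1", "O6", "N7"), x$w),
                 "two closest")
  expect_equal(sort(a@intAtoms), c("N1", "N7", "O6"))  # atoms recorded
  expect_equal(a@edge, "WC")        # decided by the two closest (N1, O6)
})

test_that("assignments never cite atoms outside the chemical graph", {
  tp <- residueTemplate("G")
  x <- mkNtWater("G", tp["N7", ] + c(0, 0, 2.8))
  expect_error(assignEdge(x$s, x$nt, "N4", x$w), "not present")
})

test_that("determinism: identical inputs give identical assignments", {
  p <- generateEdgeProbe("rG", "N2", 0.5, tempfile(fileext = ".pdb"))
  s <- readStructure(p$path)
  w <- atoms(s)[atoms(s)$resclass == "WATER", ]
  a1 <- assignEdge(s, p$nt, "N2", c(w$x, w$y, w$z))
  a2 <- assignEdge(s, p$nt, "N2", c(w$x, w$y, w$z))
  expect_equal(a1@edge, a2@edge)
  expect_equal(a1@method, a2@method)
})
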