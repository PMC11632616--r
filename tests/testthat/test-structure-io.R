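test_that("residue names classify into the four residue classes", {
  expect_equal(classifyResidue(c("HOH", "WAT", "A", "U", "ALA", "ARG")),
               c("WATER", "WATER", "RIBONUCLEOTIDE", "RIBONUCLEOTIDE",
                 "AMINO_ACID", "AMINO_ACID"))
  ## modified nucleotides, DNA and ligands are out of scope
  expect_equal(classifyResidue(c("PSU", "DA", "MG", "1MA")),
               rep("OTHER", 4))
})

test_that("atom-name dialects normalize to one prime convention", {
  expect_equal(canonicalAtomName(c("O2*", "O2'", "O2′")),
               rep("O2'", 3))
  expect_equal(canonicalAtomName(c("O1P", "O2P", "ND2")),
               c("OP1", "OP2", "ND2"))
})

test_that("hand-written PDB text parses with classes, primes and models", {
  pdb <- c(
    "MODEL        1",
    "ATOM      1  N   ARG A  10      10.000  10.000  10.000  1.00 20.00           N",
    "ATOM      2  CA  ARG A  10      11.460  10.000  10.000  1.00 20.00           C",
    "ATOM      3  C1* A   B   5       0.000   0.000   0.000  1.00 15.00           C",
    "ATOM      4  O2* A   B   5       1.300  -2.200   0.400  1.00 15.00           O",
    "HETATM    5  O   HOH W   1       5.000   5.000   5.000  1.00 30.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ARG A  10      90.000  10.000  10.000  1.00 20.00           N",
    "ATOM      2  CA  ARG A  10      91.460  10.000  10.000  1.00 20.00           C",
    "ATOM      3  C1* A   B   5      80.000   0.000   0.000  1.00 15.00           C",
    "ATOM      4  O2* A   B   5      81.300  -2.200   0.400  1.00 15.00           O",
    "HETATM    5  O   HOH W   1      85.000   5.000   5.000  1.00 30.00           O",
    "ENDMDL",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- readStructure(f)
  rt <- residueTable(s)
  expect_equal(nrow(rt), 3)
  expect_setequal(rt$resclass,
                  c("AMINO_ACID", "RIBONUCLEOTIDE", "WATER"))
  a <- atoms(s)
  expect_true("O2'" %in% a$atom)          # O2* dialect normalized
  expect_false(any(grepl("\\*", a$atom)))
  ## model 1 retained by default
  expect_equal(a$x[a$atom == "O" & a$resclass == "WATER"], 5)
  s2 <- readStructure(f, model = 2)
  expect_equal(atoms(s2)$x[atoms(s2)$atom == "O" &
                             atoms(s2)$resclass == "WATER"], 85)
  expect_error(readStructure(f, model = 3), "model")
})

test_that("altloc resolves to the highest-occupancy conformer", {
  pdb <- c(
    "ATOM      1  OG ASER A  10      10.000  10.000  10.000  0.40 20.00           O",
    "ATOM      2  OG BSER A  10      12.000  10.000  10.000  0.60 20.00           O",
    "ATOM      3  CB  SER A  10      11.000  11.000  10.000  1.00 20.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  a <- atoms(readStructure(f))
  expect_equal(sum(a$atom == "OG"), 1)
  expect_equal(a$x[a$atom == "OG"], 12)   # the B conformer at occ 0.60
})

test_that("moiety partition is total and unique over nt polar atoms", {
  expect_equal(moietyOf("rA", "OP1"), "Ph")
  expect_equal(moietyOf("G", "N7"), "Nb")
  expect_equal(moietyOf("rC", "O2'"), "Rb")
  expect_equal(moietyOf("U", "XX9"), "UNKNOWN_ATOM")
  for (nt in c("A", "C", "G", "U")) {
    tp <- residueTemplate(nt)
    m <- moietyOf(nt, rownames(tp))
    expect_true(all(m %in% c("Nb", "Ph", "Rb")),
                info = paste("moiety partition total for", nt))
  }
})

test_that("chain part is total over amino-acid atoms", {
  expect_equal(chainPartOf("SER", "OG"), "s")
  expect_equal(chainPartOf("GLY", "O"), "m")
  expect_equal(chainPartOf("ARG", c("NH1", "N")), c("s", "m"))
  for (aa in HydroBridge:::AMINO_ACIDS_3L) {
    tp <- residueTemplate(aa)
    expect_true(all(chainPartOf(aa, rownames(tp)) %in% c("m", "s")))
  }
})

test_that("write + re-read round-trips residues, atoms and classes", {
  mf <- fixtureManifest(list(bridgeSpec("A1:w:N1"),
                             bridgeSpec("A1:w:N2", cyclic = TRUE)),
                        seed = 42)
  fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
  s1 <- readStructure(fx$path)
  f2 <- tempfile(fileext = ".pdb")
  writeStructurePDB(s1, f2)
  s2 <- readStructure(f2)
  a1 <- atoms(s1); a2 <- atoms(s2)
  expect_equal(a1$resid, a2$resid)
  expect_equal(a1$atom, a2$atom)
  expect_equal(a1$resclass, a2$resclass)
  expect_equal(a1[, c("x", "y", "z", "b", "occ")],
               a2[, c("x", "y", "z", "b", "occ")], tolerance = 1e-6)
})

test_that("a structure without waters is valid and yields no bridges", {
  tp <- residueTemplate("ARG")
  s <- structureFromAtoms(chain = "A", resno = 1, resname = "ARG",
                          atom = rownames(tp), x = tp[, 1], y = tp[, 2],
                          z = tp[, 3])
  expect_s4_class(s, "RnpStructure")
  expect_length(surveyStructure(s), 0)
})
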