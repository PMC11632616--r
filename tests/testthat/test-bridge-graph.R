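# Synthetic bond tables for graph-level unit tests (no geometry needed:
# bridge construction is defined purely on the classified bond list).
mkBond <- function(donResid, donName, donAtom, donClass,
                   accResid, accName, accAtom, accClass) {
  data.frame(don_resid = donResid, don_resname = donName,
             don_atom = donAtom, don_class = donClass,
             acc_resid = accResid, acc_resname = accName,
             acc_atom = accAtom, acc_class = accClass,
             da = 2.9, ha = NA_real_, dha = NA_real_,
             kind = HydroBridge:::.bondKind(donClass, accClass),
             stringsAsFactors = FALSE)
}

test_that("bridging waters are those bonded to both classes", {
  b <- rbind(
    mkBond("W/1/HOH", "HOH", "O", "WATER", "B/1/A", "A", "N1",
           "RIBONUCLEOTIDE"),
    mkBond("A/1/ARG", "ARG", "NH1", "AMINO_ACID", "W/1/HOH", "HOH", "O",
           "WATER"),
    mkBond("W/2/HOH", "HOH", "O", "WATER", "B/1/A", "A", "N3",
           "RIBONUCLEOTIDE"),
    mkBond("W/2/HOH", "HOH", "O", "WATER", "B/2/G", "G", "O6",
           "RIBONUCLEOTIDE"))
  expect_equal(findBridgingWaters(b), "W/1/HOH")   # W/2 has no protein
  expect_equal(findBridgingWaters(b[0, ]), character(0))
})

test_that("buildBridge collapses duplicate bonds and labels topology", {
  b <- rbind(
    mkBond("W/1/HOH", "HOH", "O", "WATER", "B/1/A", "A", "N1",
           "RIBONUCLEOTIDE"),
    mkBond("W/1/HOH", "HOH", "O", "WATER", "B/1/A", "A", "N6",
           "RIBONUCLEOTIDE"),       # second bond to the same residue
    mkBond("A/1/ARG", "ARG", "NH1", "AMINO_ACID", "W/1/HOH", "HOH", "O",
           "WATER"))
  br <- buildBridge("W/1/HOH", b, waterB = 31)
  expect_equal(br@label, "A1:w:N1")
  expect_equal(br@order, 3L)
  expect_equal(br@degree, 2L)
  expect_false(br@cyclic)
  expect_equal(nrow(br@waterBonds), 3)   # all bonds retained
  expect_length(br@ntMembers, 1)         # but one member

  ## a direct member-member bond flips the cyclic flag
  b2 <- rbind(b, mkBond("A/1/ARG", "ARG", "NH2", "AMINO_ACID",
                        "B/1/A", "A", "N7", "RIBONUCLEOTIDE"))
  br2 <- buildBridge("W/1/HOH", b2)
  expect_true(br2@cyclic)
  expect_equal(br2@label, "cyc-A1:w:N1")

  ## a protein-RNA bond outside the membership does not
  b3 <- rbind(b, mkBond("A/9/LYS", "LYS", "NZ", "AMINO_ACID",
                        "B/1/A", "A", "OP1", "RIBONUCLEOTIDE"))
  expect_false(buildBridge("W/1/HOH", b3)@cyclic)

  expect_error(buildBridge("W/2/HOH", b), "not a bridging water")
})

test_that("quartet membership gives A2:w:N1 with order 4", {
  b <- rbind(
    mkBond("W/1/HOH", "HOH", "O", "WATER", "B/1/A", "A", "N1",
           "RIBONUCLEOTIDE"),
    mkBond("A/1/ARG", "ARG", "NH1", "AMINO_ACID", "W/1/HOH", "HOH", "O",
           "WATER"),
    mkBond("A/2/SER", "SER", "OG", "AMINO_ACID", "W/1/HOH", "HOH", "O",
           "WATER"))
  br <- buildBridge("W/1/HOH", b)
  expect_equal(br@label, "A2:w:N1")
  expect_equal(br@order, 4L)
})

test_that("surveyStructure returns one bridge per bridging water", {
  mf <- fixtureManifest(list(bridgeSpec("A1:w:N1"),
                             bridgeSpec("A1:w:N2")), seed = 3)
  fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
  set <- surveyStructure(readStructure(fx$path))
  expect_length(set, 2)
  expect_setequal(vapply(bridges(set), function(b) b@label, character(1)),
                  c("A1:w:N1", "A1:w:N2"))
})

test_that("theoretical class enumeration is pure combinatorics", {
  for (cyc in c(FALSE, TRUE)) {
    cc <- enumerateTheoreticalClasses("A1wN1", cyclic = cyc)
    expect_equal(cc$single_portion + cc$dual_portion, cc$total)
  }
  expect_error(enumerateTheoreticalClasses("A2wN1"), "A1:w:N1")
})

test_that("multiplet invariants hold across the ensemble", {
  ens <- ensembleFixture()
  brs <- bridges(ens$set)
  waters <- vapply(brs, function(b) b@water, character(1))
  expect_equal(anyDuplicated(waters), 0)   # one bridge per water
  for (b in brs) {
    expect_gte(b@order, 3L)
    expect_equal(b@order, b@degree + 1L)
    expect_equal(b@order,
                 length(b@aaMembers) + length(b@ntMembers) + 1L)
    expect_equal(b@cyclic, nrow(b@directBonds) > 0)
    inc <- HydroBridge:::.waterIncidence(b@waterBonds)
    expect_setequal(unique(inc$partner),
                    c(b@aaMembers, b@ntMembers))
  }
  ## conservation: member counts equal distinct bonded (water, residue)
  ## pairs on each side
  inc <- HydroBridge:::.waterIncidence(ens$set@hbonds)
  inc <- inc[inc$water %in% waters, ]
  aaPairs <- unique(inc[inc$partner_class == "AMINO_ACID",
                        c("water", "partner")])
  ntPairs <- unique(inc[inc$partner_class == "RIBONUCLEOTIDE",
                        c("water", "partner")])
  expect_equal(sum(vapply(brs, function(b) length(b@aaMembers),
                          integer(1))), nrow(aaPairs))
  expect_equal(sum(vapply(brs, function(b) length(b@ntMembers),
                          integer(1))), nrow(ntPairs))
  ## over-tetrahedral waters are retained and flagged
  nb <- vapply(brs, function(b) nrow(b@waterBonds), integer(1))
  ot <- vapply(brs, function(b) b@overTetrahedral, logical(1))
  expect_equal(ot, nb > 4)
  expect_true(any(ot))
})
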