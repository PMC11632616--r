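test_that("survey aggregation recovers the generator manifest", {
  ens <- ensembleFixture()
  sm <- aggregateSurvey(list(ens$inv))
  fx <- ens$fx
  expect_equal(sm@nBridges, nrow(fx$bridges))
  expect_equal(sm@nBridgingWaters, fx$counts$nBridgingWaters)
  expect_equal(sm@nWatersTotal, fx$counts$nWaters)

  ## topology frequencies equal the manifest exactly
  expTopo <- as.data.frame(table(label = fx$bridges$label),
                           stringsAsFactors = FALSE)
  gotTopo <- sm@topologyFreq
  expect_equal(gotTopo$count[match(expTopo$label, gotTopo$label)],
               expTopo$Freq)

  ## bond-level nucleotide counts equal the manifest bond table
  expNt <- table(HydroBridge:::NT_DISPLAY[fx$ntBonds$resname])
  gotNt <- stats::setNames(sm@bondsByNucleotide$count,
                           sm@bondsByNucleotide$nt)
  expect_equal(gotNt[names(expNt)], as.table(expNt)[names(expNt)],
               ignore_attr = TRUE)

  ## amino-acid bond counts likewise
  expAa <- table(fx$aaBonds$resname)
  gotAa <- stats::setNames(sm@bondsByAminoAcid$count,
                           sm@bondsByAminoAcid$aa)
  expect_equal(gotAa[names(expAa)], as.table(expAa)[names(expAa)],
               ignore_attr = TRUE)

  ## B-factor means match the manifest exactly
  bf <- stats::setNames(sm@bfactorStats$value, sm@bfactorStats$statistic)
  expect_equal(unname(bf["mean_b_bridging_waters"]),
               fx$counts$meanBBridging)
  expect_equal(unname(bf["mean_b_all_waters"]), fx$counts$meanBAll)
})

test_that("percentage tables are consistent", {
  ens <- ensembleFixture()
  sm <- aggregateSurvey(list(ens$inv))
  for (tb in list(sm@bondsByNucleotide, sm@bondsByMoiety,
                  sm@bondsByAminoAcid, sm@bondsByChainPart))
    expect_lt(abs(sum(tb$pct) - 100), 0.1)
  nt <- stats::setNames(sm@bondsByNucleotide$pct, sm@bondsByNucleotide$nt)
  purine <- nt[["rA"]] + nt[["rG"]]
  pyrimidine <- nt[["rC"]] + nt[["rU"]]
  expect_lt(abs(purine + pyrimidine - 100), 0.1)
})

test_that("the pair matrix counts co-membership once per pair", {
  ens <- ensembleFixture()
  sm <- aggregateSurvey(list(ens$inv))
  expTotal <- sum(vapply(bridges(ens$set), function(b)
    length(b@aaMembers) * length(b@ntMembers), integer(1)))
  expect_equal(sum(sm@pairMatrix), expTotal)
  expect_equal(dim(sm@pairMatrix), c(20L, 4L))
})

test_that("triplet class table keys match nomenclature terms", {
  ens <- ensembleFixture()
  ct <- tripletClassTable(list(ens$inv))
  expect_true(all(ct$count >= 1))
  ## the two named exemplar classes are present in the right tables
  acy <- ct[!ct$cyclic, ]
  expect_true(any(acy$aa == "Arg" & acy$portion == "s" &
                    acy$nt == "rA" & acy$edge == "SG"))
  cyc <- ct[ct$cyclic, ]
  expect_true(any(cyc$aa == "Glu" & cyc$portion == "s" &
                    cyc$nt == "rG" & cyc$edge == "WC"))
  ## only nucleobase-mediated A1:w:N1 bridges are tabulated
  bd <- ens$inv$bridgeDf
  nTrip <- sum(vapply(seq_len(nrow(bd)), function(i) {
    if (bd$topo[i] != "A1:w:N1") return(FALSE)
    e <- ens$fx$ntEdges
    e$edge[e$water == bd$water[i]] %in% c("WC", "HG", "SG")
  }, logical(1)))
  expect_equal(sum(ct$count), nTrip)
  ## keys are a subset of the 672 theoretical classes
  expect_lte(nrow(unique(ct[, c("aa", "portion", "nt", "edge")])),
             enumerateTheoreticalClasses()$total)
})

test_that("one-bridge survey gives 100% to its nucleotide", {
  mf <- fixtureManifest(list(bridgeSpec("A1:w:N1")), seed = 12,
                        decoyWaters = 2L, decoyBonds = 0L)
  fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
  s <- readStructure(fx$path)
  inv <- annotateBridges(surveyStructure(s), s)
  sm <- aggregateSurvey(list(inv))
  nt <- stats::setNames(sm@bondsByNucleotide$pct, sm@bondsByNucleotide$nt)
  expect_equal(unname(nt[["rA"]]), 100)
  ## B-factor mixture mean is plain arithmetic over water oxygens
  expect_equal(sm@bfactorStats$value[
    sm@bfactorStats$statistic == "mean_b_all_waters"],
    mean(c(fx$bridges$waterB, mf$decoyWaterB[1:2])))
})

test_that("reports are deterministic and handle empty inventories", {
  ens <- ensembleFixture()
  sm <- aggregateSurvey(list(ens$inv))
  ct <- tripletClassTable(list(ens$inv))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  f1 <- writeReports(sm, ct, d1)
  f2 <- writeReports(sm, ct, d2)
  for (k in seq_along(f1))
    expect_equal(readLines(f1[k]), readLines(f2[k]))

  ## a water-only structure yields zero bridges and header-only tables
  s0 <- structureFromAtoms(chain = "W", resno = 1, resname = "HOH",
                           atom = "O", x = 0, y = 0, z = 0, b = 40)
  inv0 <- annotateBridges(surveyStructure(s0), s0)
  sm0 <- aggregateSurvey(list(inv0))
  expect_equal(sm0@nBridges, 0L)
  expect_equal(sm0@nWatersTotal, 1L)
  d0 <- file.path(tempdir(), "rep0")
  f0 <- writeReports(sm0, tripletClassTable(list(inv0)), d0)
  tf <- grep("topology_freq", f0, value = TRUE)
  expect_equal(length(readLines(tf)), 1)   # header only
})

test_that("bridge inventories export as JSON-lines and TSV", {
  ens <- ensembleFixture()
  jl <- tempfile(fileext = ".jsonl"); tv <- tempfile(fileext = ".tsv")
  writeBridgeInventory(ens$inv, jl, tv)
  lines <- readLines(jl)
  expect_length(lines, nrow(ens$inv$bridgeDf))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("water", "label", "cyclic", "name", "aa_members",
                    "nt_members") %in% names(rec)))
  tsv <- utils::read.delim(tv)
  expect_equal(nrow(tsv), nrow(ens$inv$bridgeDf))
})
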