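## Aggregation of per-structure bridge inventories into survey
## statistics: per-residue hydrogen-bond frequency tables (counting
## unit: one water-to-residue-atom bond), topology frequencies
## (counting unit: bridges), the amino acid x ribonucleotide
## co-membership matrix, B-factor statistics, and the triplet class
## table keyed by the nomenclature terms.

#' Annotate a bridge set for aggregation
#'
#' Attaches edge assignments, portions and rendered names to every
#' bridge of a [WaterBridgeSet-class], producing the flat per-structure
#' inventory consumed by [aggregateSurvey()] and
#' [tripletClassTable()].
#'
#' @param set a [WaterBridgeSet-class].
#' @param structure the corresponding [RnpStructure-class].
#' @param tables edge-rule tables.
#' @return a list of class `"bridgeInventory"` with elements
#'   `structureId`, `bridgeDf` (one row per bridge: water, label, topo,
#'   cyclic, order, name, waterB, overTetrahedral), `aaBonds` and
#'   `ntBonds` (one row per water hydrogen bond on each side),
#'   `pairs` (aa x nt co-membership, once per pair per bridge),
#'   `tripletRows` (nucleobase-mediated `A1:w:N1` classes) and
#'   `waterB` (B-factor of every water O in the model).
#' @export
annotateBridges <- function(set, structure, tables = edgePairTables()) {
  brs <- bridges(set)
  empty <- list(
    structureId = set@structureId,
    bridgeDf = data.frame(water = character(0), label = character(0),
                          topo = character(0), cyclic = logical(0),
                          order = integer(0), name = character(0),
                          waterB = numeric(0),
                          overTetrahedral = logical(0)),
    aaBonds = data.frame(water = character(0), resid = character(0),
                         resname = character(0), atom = character(0),
                         part = character(0)),
    ntBonds = data.frame(water = character(0), resid = character(0),
                         resname = character(0), atom = character(0),
                         moiety = character(0)),
    pairs = data.frame(water = character(0), aa = character(0),
                       nt = character(0)),
    tripletRows = data.frame(aa = character(0), portion = character(0),
                             nt = character(0), edge = character(0),
                             cyclic = logical(0)),
    waterB = set@waterB)
  class(empty) <- "bridgeInventory"
  if (!length(brs)) return(empty)

  rows <- lapply(brs, function(b) {
    asg <- classifyBridgeContacts(b, structure, tables)
    nm <- renderName(b, asg)
    inc <- .waterIncidence(b@waterBonds)
    aaRows <- inc[inc$partner_class == "AMINO_ACID", , drop = FALSE]
    ntRows <- inc[inc$partner_class == "RIBONUCLEOTIDE", , drop = FALSE]
    aaB <- data.frame(water = b@water, resid = aaRows$partner,
                      resname = aaRows$partner_name,
                      atom = aaRows$partner_atom,
                      part = mapply(function(rn, at)
                        chainPartOf(rn, at), aaRows$partner_name,
                        aaRows$partner_atom, USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
    ntB <- data.frame(water = b@water, resid = ntRows$partner,
                      resname = ntRows$partner_name,
                      atom = ntRows$partner_atom,
                      moiety = mapply(function(rn, at)
                        moietyOf(rn, at), ntRows$partner_name,
                        ntRows$partner_atom, USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
    prs <- expand.grid(aa = unique(aaRows$partner_name),
                       nt = unique(ntRows$partner_name),
                       stringsAsFactors = FALSE)
    prs <- data.frame(water = b@water, prs, stringsAsFactors = FALSE)
    topo <- sub("^cyc-", "", b@label)
    trip <- NULL
    if (topo == "A1:w:N1") {
      a1 <- asg[[b@ntMembers[1]]]
      if (a1@edge %in% c("WC", "HG", "SG"))
        trip <- data.frame(aa = nm@aaTerms$name[1],
                           portion = nm@aaTerms$portion[1],
                           nt = NT_DISPLAY[[a1@resname]],
                           edge = a1@edge, cyclic = b@cyclic,
                           stringsAsFactors = FALSE)
    }
    list(df = data.frame(water = b@water, label = b@label, topo = topo,
                         cyclic = b@cyclic, order = b@order,
                         name = nm@text, waterB = b@waterB,
                         overTetrahedral = b@overTetrahedral,
                         stringsAsFactors = FALSE),
         aaB = aaB, ntB = ntB, prs = prs, trip = trip)
  })
  bind <- function(el) {
    parts <- Filter(Negate(is.null), lapply(rows, `[[`, el))
    if (length(parts)) do.call(rbind, parts) else empty[[
      c(df = "bridgeDf", aaB = "aaBonds", ntB = "ntBonds",
        prs = "pairs", trip = "tripletRows")[el]]]
  }
  out <- list(structureId = set@structureId, bridgeDf = bind("df"),
              aaBonds = bind("aaB"), ntBonds = bind("ntB"),
              pairs = bind("prs"), tripletRows = bind("trip"),
              waterB = set@waterB)
  rownames(out$bridgeDf) <- NULL
  class(out) <- "bridgeInventory"
  out
}

.pctTable <- function(x, levels, key) {
  cnt <- table(factor(x, levels = levels))
  n <- sum(cnt)
  out <- data.frame(key = levels, count = as.integer(cnt),
                    pct = if (n) round(100 * as.integer(cnt) / n, 1)
                          else rep(0, length(levels)))
  names(out)[1] <- key
  out
}

#' Aggregate bridge inventories into survey statistics
#'
#' Residue-level frequency tables count hydrogen bonds (one
#' water-to-residue-atom bond is one count); topology tables count
#' bridges; B-factor means weight each water oxygen once. Percentages
#' are reported to one decimal.
#'
#' @param inventories list of inventories from [annotateBridges()].
#' @return a [SurveySummary-class].
#' @export
aggregateSurvey <- function(inventories) {
  if (inherits(inventories, "bridgeInventory"))
    inventories <- list(inventories)
  if (!length(inventories))
    stop("aggregateSurvey() needs at least one inventory")
  bd <- do.call(rbind, lapply(inventories, `[[`, "bridgeDf"))
  aaB <- do.call(rbind, lapply(inventories, `[[`, "aaBonds"))
  ntB <- do.call(rbind, lapply(inventories, `[[`, "ntBonds"))
  prs <- do.call(rbind, lapply(inventories, `[[`, "pairs"))
  allWaterB <- unlist(lapply(inventories, `[[`, "waterB"))

  ntLevels <- unname(NT_DISPLAY[RIBONUCLEOTIDES])
  bondsByNucleotide <- .pctTable(NT_DISPLAY[ntB$resname], ntLevels, "nt")
  bondsByMoiety <- .pctTable(ntB$moiety, c("Nb", "Ph", "Rb"), "moiety")
  bondsByAminoAcid <- .pctTable(aaB$resname, AMINO_ACIDS_3L, "aa")
  bondsByChainPart <- .pctTable(aaB$part, c("m", "s"), "part")

  pairMatrix <- matrix(0L, nrow = length(AMINO_ACIDS_3L), ncol = 4,
                       dimnames = list(AMINO_ACIDS_3L, ntLevels))
  if (nrow(prs)) {
    t2 <- table(factor(prs$aa, levels = AMINO_ACIDS_3L),
                factor(NT_DISPLAY[prs$nt], levels = ntLevels))
    pairMatrix[] <- as.integer(t2)
  }

  topologyFreq <- if (nrow(bd)) {
    t3 <- as.data.frame(table(label = bd$label), stringsAsFactors = FALSE)
    names(t3)[2] <- "count"
    t3$cyclic <- startsWith(t3$label, "cyc-")
    t3[order(t3$label), c("label", "cyclic", "count")]
  } else data.frame(label = character(0), cyclic = logical(0),
                    count = integer(0))

  perOrder <- if (nrow(bd))
    vapply(split(bd$waterB, bd$order), mean, numeric(1))
  else numeric(0)
  bfactorStats <- rbind(
    data.frame(statistic = "mean_b_bridging_waters",
               value = if (nrow(bd)) mean(bd$waterB) else NA_real_),
    data.frame(statistic = "mean_b_all_waters",
               value = if (length(allWaterB)) mean(allWaterB)
                       else NA_real_),
    if (length(perOrder))
      data.frame(statistic = paste0("mean_b_order_", names(perOrder)),
                 value = unname(perOrder)))

  new("SurveySummary",
      nStructures = length(inventories),
      nWatersTotal = length(allWaterB),
      nBridgingWaters = as.integer(NROW(bd)),
      nBridges = as.integer(NROW(bd)),
      bondsByNucleotide = bondsByNucleotide,
      bondsByMoiety = bondsByMoiety,
      bondsByAminoAcid = bondsByAminoAcid,
      bondsByChainPart = bondsByChainPart,
      pairMatrix = pairMatrix, topologyFreq = topologyFreq,
      bfactorStats = bfactorStats)
}

#' Triplet class table
#'
#' Frequency of nucleobase-mediated `A1:w:N1` (and cyclic) bridges per
#' (amino acid, portion, ribonucleotide, edge) class; keys match the
#' nomenclature terms. Higher-order bridges and non-nucleobase triplets
#' are out of scope for this table.
#'
#' @param inventories list of inventories from [annotateBridges()].
#' @return data.frame (`aa`, `portion`, `nt`, `edge`, `cyclic`,
#'   `count`), sorted.
#' @export
tripletClassTable <- function(inventories) {
  if (inherits(inventories, "bridgeInventory"))
    inventories <- list(inventories)
  tr <- do.call(rbind, lapply(inventories, `[[`, "tripletRows"))
  if (is.null(tr) || !nrow(tr))
    return(data.frame(aa = character(0), portion = character(0),
                      nt = character(0), edge = character(0),
                      cyclic = logical(0), count = integer(0)))
  agg <- stats::aggregate(list(count = rep(1L, nrow(tr))),
                          tr[, c("aa", "portion", "nt", "edge", "cyclic")],
                          FUN = sum)
  agg <- agg[order(agg$cyclic, agg$aa, agg$portion, agg$nt, agg$edge), ]
  rownames(agg) <- NULL
  agg
}

#' Write survey reports
#'
#' Writes one TSV per frequency table, the triplet class tables (split
#' acyclic/cyclic), and a single JSON file with the full summary.
#' Output is deterministic: re-running on the same input is
#' byte-identical.
#'
#' @param summary a [SurveySummary-class].
#' @param classTable output of [tripletClassTable()].
#' @param outDir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
writeReports <- function(summary, classTable, outDir) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  wtsv <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    p
  }
  files <- c(
    wtsv(summary@bondsByNucleotide, "bonds_by_nucleotide.tsv"),
    wtsv(summary@bondsByMoiety, "bonds_by_moiety.tsv"),
    wtsv(summary@bondsByAminoAcid, "bonds_by_amino_acid.tsv"),
    wtsv(summary@bondsByChainPart, "bonds_by_chain_part.tsv"),
    wtsv(as.data.frame(summary@pairMatrix), "pair_matrix.tsv"),
    wtsv(summary@topologyFreq, "topology_freq.tsv"),
    wtsv(summary@bfactorStats, "bfactor_stats.tsv"),
    wtsv(classTable[!classTable$cyclic, , drop = FALSE],
         "triplet_classes_acyclic.tsv"),
    wtsv(classTable[classTable$cyclic, , drop = FALSE],
         "triplet_classes_cyclic.tsv"))
  js <- list(
    n_structures = summary@nStructures,
    n_waters_total = summary@nWatersTotal,
    n_bridging_waters = summary@nBridgingWaters,
    n_bridges = summary@nBridges,
    bonds_by_nucleotide = summary@bondsByNucleotide,
    bonds_by_moiety = summary@bondsByMoiety,
    bonds_by_amino_acid = summary@bondsByAminoAcid,
    bonds_by_chain_part = summary@bondsByChainPart,
    pair_matrix = summary@pairMatrix,
    topology_freq = summary@topologyFreq,
    bfactor_stats = summary@bfactorStats)
  jsPath <- file.path(outDir, "survey_summary.json")
  jsonlite::write_json(js, jsPath, dataframe = "rows", matrix = "rowmajor",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, jsPath))
}

#' Write a per-structure bridge inventory
#'
#' Emits the bridge inventory as JSON-lines (one bridge per line:
#' water, members, label, cyclic flag, name, B-factor) and a TSV
#' summary.
#'
#' @param inventory output of [annotateBridges()].
#' @param jsonlPath,tsvPath output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
writeBridgeInventory <- function(inventory, jsonlPath = NULL,
                                 tsvPath = NULL) {
  bd <- inventory$bridgeDf
  if (!is.null(jsonlPath)) {
    lines <- vapply(seq_len(nrow(bd)), function(i) {
      aa <- unique(inventory$aaBonds$resid[
        inventory$aaBonds$water == bd$water[i]])
      nt <- unique(inventory$ntBonds$resid[
        inventory$ntBonds$water == bd$water[i]])
      jsonlite::toJSON(list(structure = inventory$structureId,
                            water = bd$water[i], label = bd$label[i],
                            cyclic = bd$cyclic[i], name = bd$name[i],
                            water_b = bd$waterB[i],
                            over_tetrahedral = bd$overTetrahedral[i],
                            aa_members = aa, nt_members = nt),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, jsonlPath)
  }
  if (!is.null(tsvPath))
    utils::write.table(bd, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  invisible(c(jsonlPath, tsvPath))
}
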