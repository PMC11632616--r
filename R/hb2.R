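## Ingestion of HBPLUS .hb2 hydrogen-bond lists, resolved against a
## parsed structure so downstream classification is identical to the
## native detection route.

.parseHB2Block <- function(block) {
  ## One 14-column atom block: chain(1) resno(4) ins(1) resname(3)
  ## space atom(4).
  list(chain = substr(block, 1, 1),
       resno = suppressWarnings(as.integer(substr(block, 2, 5))),
       ins = gsub("-", "", substr(block, 6, 6)),
       resname = toupper(trimws(substr(block, 7, 9))),
       atom = canonicalAtomName(substr(block, 11, 14)))
}

#' Read an HBPLUS .hb2 hydrogen-bond list
#'
#' Parses the fixed-width records of an HBPLUS `.hb2` output file and
#' resolves each donor/acceptor against the residues of `structure`, so
#' the returned bonds carry the same `kind` classification as native
#' [detectHBonds()] output. Records naming residues absent from the
#' structure, and malformed records, are skipped with a warning. Of the
#' trailing numeric fields only the D-A distance, D-H-A angle and H-A
#' distance are consumed (HBPLUS writes `-1` sentinels when a value is
#' undefined; these become `NA`).
#'
#' @param path `.hb2` file path.
#' @param structure the [RnpStructure-class] the file was computed from.
#' @param waterNames residue names treated as water.
#' @return data.frame in the same layout as [detectHBonds()].
#' @export
readHB2 <- function(path, structure, waterNames = DEFAULT_WATER_NAMES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  dataLines <- grep("^[A-Za-z0-9-][ 0-9]{3}[0-9]", lines, value = TRUE)
  rt <- residueTable(structure)
  rkey <- paste(rt$chain, rt$resno, rt$ins)
  out <- vector("list", length(dataLines))
  skipped <- 0L
  for (k in seq_along(dataLines)) {
    ln <- dataLines[k]
    if (nchar(ln) < 33) { skipped <- skipped + 1L; next }
    don <- .parseHB2Block(substr(ln, 1, 14))
    acc <- .parseHB2Block(substr(ln, 15, 28))
    toks <- strsplit(trimws(substring(ln, 29)), "\\s+")[[1]]
    if (is.na(don$resno) || is.na(acc$resno) || length(toks) < 1 ||
        is.na(suppressWarnings(as.numeric(toks[1])))) {
      skipped <- skipped + 1L; next
    }
    num <- function(s) {
      v <- suppressWarnings(as.numeric(s))
      if (length(v) != 1 || is.na(v) || v < 0) NA_real_ else v
    }
    da <- num(toks[1])
    dha <- if (length(toks) >= 5) num(toks[5]) else NA_real_
    ha <- if (length(toks) >= 6) num(toks[6]) else NA_real_

    di <- match(paste(don$chain, don$resno, don$ins), rkey)
    ai <- match(paste(acc$chain, acc$resno, acc$ins), rkey)
    nameOk <- function(idx, blk) {
      !is.na(idx) && (rt$resname[idx] == blk$resname ||
                      (rt$resclass[idx] == "WATER" &&
                       blk$resname %in% waterNames))
    }
    if (!nameOk(di, don) || !nameOk(ai, acc)) {
      skipped <- skipped + 1L; next
    }
    out[[k]] <- data.frame(
      don_resid = rt$resid[di], don_resname = rt$resname[di],
      don_atom = don$atom, don_class = rt$resclass[di],
      acc_resid = rt$resid[ai], acc_resname = rt$resname[ai],
      acc_atom = acc$atom, acc_class = rt$resclass[ai],
      da = da, ha = ha, dha = dha,
      kind = .bondKind(rt$resclass[di], rt$resclass[ai]),
      stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " .hb2 record(s) skipped (malformed or naming ",
            "residues absent from the structure)")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(.emptyBondTable())
  pairKey <- apply(cbind(paste(res$don_resid, res$don_atom),
                         paste(res$acc_resid, res$acc_atom)), 1,
                   function(r) paste(sort(r), collapse = " | "))
  res <- res[!duplicated(pairKey), , drop = FALSE]
  res <- res[order(res$don_resid, res$don_atom, res$acc_resid,
                   res$acc_atom), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Write a bond table in .hb2 layout (fixture/testing aid mirroring the
## HBPLUS record format).
.writeHB2 <- function(bonds, structure, path) {
  rt <- residueTable(structure)
  blk <- function(resid, atom) {
    r <- rt[rt$resid == resid, ][1, ]
    sprintf("%s%04d%s%3s %-4s", r$chain, r$resno,
            if (r$ins == "") "-" else r$ins,
            substr(r$resname, 1, 3), substr(atom, 1, 4))
  }
  hdr <- c("HBPLUS Hydrogen Bond Calculator (fixture)",
           rep("*", 7))
  recs <- vapply(seq_len(nrow(bonds)), function(k) {
    b <- bonds[k, ]
    sprintf("%s%s%5.2f %-3s %3d %5.2f %5.1f %5.1f %5.1f %5.1f %5d",
            blk(b$don_resid, b$don_atom), blk(b$acc_resid, b$acc_atom),
            b$da, "??", -2,
            -1, if (is.na(b$dha)) -1 else b$dha,
            if (is.na(b$ha)) -1 else b$ha, -1, -1, k)
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
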