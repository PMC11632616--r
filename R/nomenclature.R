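## Systematic bridge nomenclature, e.g.
##   cyc-Thr(s)|Gly(m):w:rU(Ph)|rC(Rb)|rG(Rb)
## Amino acids sit left of the central ":w:" token: main-chain (m) terms
## immediately left, then ms, then side-chain (s) terms, descending
## alphabetical within each group reading left to right. Ribonucleotides
## sit right of ":w:": nucleobase terms first (WC, then HG, then SG
## edge), then phosphate, then ribose, alphabetical within each group.

#' Rendered systematic bridge name
#'
#' @slot cyclic logical; renders the `cyc-` prefix.
#' @slot aaTerms data.frame (`name`, `portion`) in rendered order.
#' @slot ntTerms data.frame (`name`, `annotation`) in rendered order.
#' @slot text the rendered string.
#' @export
setClass("BridgeName",
         representation(cyclic = "logical", aaTerms = "data.frame",
                        ntTerms = "data.frame", text = "character"))

setMethod("show", "BridgeName", function(object) {
  cat(object@text, "\n")
})

.titleCase <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

## Portion (m/s/ms) of each amino-acid member of a bridge, derived from
## the chain part of the atoms it bonds to the bridging water.
#' Amino-acid portions of a bridge's members
#'
#' For each amino-acid member, whether it contacts the bridging water
#' through its main chain (`"m"`), side chain (`"s"`) or both (`"ms"`).
#'
#' @param bridge a [WaterBridge-class].
#' @return named character vector over the aa members.
#' @export
aaPortions <- function(bridge) {
  inc <- .waterIncidence(bridge@waterBonds)
  vapply(bridge@aaMembers, function(m) {
    rows <- inc[inc$partner == m, ]
    parts <- unique(chainPartOf(rows$partner_name[1], rows$partner_atom))
    if (length(parts) == 2) "ms" else parts
  }, character(1))
}

#' Annotation of a nucleotide contact
#'
#' The term annotation used in names: the nucleobase edge when one was
#' assigned (`WC`/`HG`/`SG`, including `O2'`-alone SG semantics),
#' otherwise the moiety (`Ph` or `Rb`).
#'
#' @param assignment an [EdgeAssignment-class].
#' @return single character annotation.
#' @export
ntAnnotation <- function(assignment) {
  if (assignment@edge != "NONE") assignment@edge else assignment@moiety
}

.renderText <- function(cyclic, aaTerms, ntTerms) {
  aa <- paste0(aaTerms$name, "(", aaTerms$portion, ")", collapse = "|")
  nt <- paste0(ntTerms$name, "(", ntTerms$annotation, ")", collapse = "|")
  paste0(if (cyclic) "cyc-" else "", aa, ":w:", nt)
}

#' Render the systematic name of a water bridge
#'
#' @param bridge a [WaterBridge-class].
#' @param assignments edge assignments for the nt members, as returned
#'   by [classifyBridgeContacts()].
#' @return a [BridgeName-class].
#' @examples
#' mf <- fixtureManifest(list(bridgeSpec("A1:w:N1")), seed = 3)
#' fx <- generateFixture(mf, tempfile(fileext = ".pdb"))
#' s <- readStructure(fx$path)
#' b <- bridges(surveyStructure(s))[[1]]
#' renderName(b, classifyBridgeContacts(b, s))
#' @export
renderName <- function(bridge, assignments) {
  portions <- aaPortions(bridge)
  inc <- .waterIncidence(bridge@waterBonds)
  aaName <- vapply(bridge@aaMembers, function(m)
    .titleCase(inc$partner_name[inc$partner == m][1]), character(1))
  aa <- data.frame(name = aaName, portion = unname(portions),
                   tie = bridge@aaMembers, stringsAsFactors = FALSE)
  missing <- setdiff(bridge@ntMembers, names(assignments))
  if (length(missing))
    stop("no edge assignment for member(s): ",
         paste(missing, collapse = ", "))
  nt <- data.frame(
    name = vapply(bridge@ntMembers, function(m)
      NT_DISPLAY[[assignments[[m]]@resname]], character(1)),
    annotation = vapply(bridge@ntMembers, function(m)
      ntAnnotation(assignments[[m]]), character(1)),
    tie = bridge@ntMembers, stringsAsFactors = FALSE)

  ## aa: groups left-to-right s, ms, m; descending alphabetical within.
  aa$grp <- match(aa$portion, c("s", "ms", "m"))
  aa <- aa[order(aa$grp, rank(aa$name) * -1, aa$tie), ]
  ## nt: groups left-to-right WC, HG, SG, Ph, Rb; ascending within.
  nt$grp <- match(nt$annotation, c("WC", "HG", "SG", "Ph", "Rb"))
  nt <- nt[order(nt$grp, nt$name, nt$tie), ]

  aaTerms <- aa[, c("name", "portion")]; rownames(aaTerms) <- NULL
  ntTerms <- nt[, c("name", "annotation")]; rownames(ntTerms) <- NULL
  new("BridgeName", cyclic = bridge@cyclic, aaTerms = aaTerms,
      ntTerms = ntTerms,
      text = .renderText(bridge@cyclic, aaTerms, ntTerms))
}

#' Parse a systematic bridge name
#'
#' Inverse of [renderName()] on its image. Malformed input raises an
#' error reporting the character position of the failure.
#'
#' @param text a name such as `"Arg(s):w:rA(SG)"`.
#' @return a [BridgeName-class].
#' @examples
#' parseName("cyc-Glu(s):w:rG(WC)")
#' @export
parseName <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  orig <- text
  pos <- 1L
  cyclic <- FALSE
  if (startsWith(text, "cyc-")) {
    cyclic <- TRUE
    text <- substring(text, 5)
    pos <- 5L
  }
  centre <- regexpr(":w:", text, fixed = TRUE)
  if (centre < 0)
    stop("malformed bridge name (missing ':w:' separator) at position ",
         pos, ": '", orig, "'")
  aaSide <- substr(text, 1, centre - 1)
  ntSide <- substring(text, centre + 3)

  parseTerms <- function(side, pattern, what, offset) {
    if (side == "")
      stop("malformed bridge name (empty ", what, " side) at position ",
           offset, ": '", orig, "'")
    terms <- strsplit(side, "|", fixed = TRUE)[[1]]
    at <- offset
    out <- lapply(terms, function(tm) {
      m <- regexec(pattern, tm)[[1]]
      if (m[1] < 0)
        stop("malformed ", what, " term '", tm, "' at position ", at,
             ": '", orig, "'")
      g <- regmatches(tm, regexec(pattern, tm))[[1]]
      at <<- at + nchar(tm) + 1L
      g[-1]
    })
    do.call(rbind, out)
  }
  aaPat <- "^([A-Z][a-z]{2})\\((m|s|ms)\\)$"
  ntPat <- "^(r[ACGU])\\((WC|HG|SG|Ph|Rb)\\)$"
  aaM <- parseTerms(aaSide, aaPat, "amino-acid", pos)
  ntM <- parseTerms(ntSide, ntPat, "ribonucleotide",
                    pos + nchar(aaSide) + 3L)
  badAA <- setdiff(aaM[, 1], .titleCase(AMINO_ACIDS_3L))
  if (length(badAA))
    stop("unknown amino acid '", badAA[1], "' in '", orig, "'")
  aaTerms <- data.frame(name = aaM[, 1], portion = aaM[, 2],
                        stringsAsFactors = FALSE)
  ntTerms <- data.frame(name = ntM[, 1], annotation = ntM[, 2],
                        stringsAsFactors = FALSE)
  new("BridgeName", cyclic = cyclic, aaTerms = aaTerms, ntTerms = ntTerms,
      text = orig)
}
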