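## Synthetic-fixture generation: small, geometrically valid PDB files
## realizing a requested inventory of water bridges, so that every
## pipeline stage can be tested without downloading structures. Each
## bridge occupies its own cell on a 30 Angstrom grid; residues are
## rigid idealized templates rotated so that exactly the requested
## contact atoms sit ~2.8 Angstrom from the cell's water, and every
## placement is validated against the detection criteria with a
## >= 0.2 Angstrom margin (unintended polar pairs are kept beyond
## 3.55 Angstrom). Generation fails, rather than silently degrading,
## when a request is geometrically infeasible.

.unit <- function(v) v / sqrt(sum(v^2))

.rotAxis <- function(axis, angle) {
  u <- .unit(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

.rotBetween <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    ## pick any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(.rotAxis(ref - sum(ref * a) * a, pi))
  }
  .rotAxis(c(a[2] * b[3] - a[3] * b[2],
             a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1]), acos(d))
}

.crossDist <- function(X1, X2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
  sqrt(pmax(d2, 0))
}

.compatMat <- function(r1, r2) {
  don1 <- r1 %in% c("donor", "both"); acc1 <- r1 %in% c("acceptor", "both")
  don2 <- r2 %in% c("donor", "both"); acc2 <- r2 %in% c("acceptor", "both")
  outer(don1, acc2, `&`) | outer(acc1, don2, `&`)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(matrix(x, nrow = 1))
  do.call(rbind, lapply(seq_along(x), function(i)
    cbind(x[i], .permutations(x[-i]))))
}

## Candidate slot assignments for the nucleotide members (preference
## pool: opposed/spread directions first), permuted so infeasible
## arrangements can be retried.
.slotPermutations <- function(nN) {
  pool <- c(1L, 3L, 5L, 6L, 2L, 4L)
  sub <- pool[seq_len(min(length(pool), nN + 1L))]
  perms <- .permutations(sub)[, seq_len(nN), drop = FALSE]
  perms <- perms[!duplicated(apply(perms, 1, paste, collapse = ",")), ,
                 drop = FALSE]
  perms[seq_len(min(nrow(perms), 30L)), , drop = FALSE]
}

## Ambiguous single atoms and their adjacent-atom rule, duplicated here
## from the edge-rule table on purpose: the generator's expectations
## must not be derived from the classifier under test.
.AMBIG_GEOM <- list(
  "A N6" = list(adj = c("N1", "C5"), edge = c("WC", "HG")),
  "G O6" = list(adj = c("N1", "C5"), edge = c("WC", "HG")),
  "G N2" = list(adj = c("N1", "N3"), edge = c("WC", "SG")),
  "C O2" = list(adj = c("N3", "N1"), edge = c("WC", "SG")),
  "U O2" = list(adj = c("N3", "N1"), edge = c("WC", "SG")))

.DEFAULT_SIDE_ATOM <- c(ARG = "NH1", LYS = "NZ", SER = "OG", THR = "OG1",
                        ASN = "ND2", GLN = "NE2", ASP = "OD1",
                        GLU = "OE1", HIS = "NE2", TYR = "OH",
                        TRP = "NE1", CYS = "SG", MET = "SD")

.DEFAULT_NT_ATOMS <- function(res, annotation) {
  switch(annotation,
    WC = switch(res, A = "N1", G = "N1", C = "N3", U = "N3"),
    HG = if (res %in% c("A", "G")) "N7"
         else stop("Hoogsteen contacts are infeasible for pyrimidines (",
                   res, ")"),
    SG = if (res %in% c("A", "G")) "N3" else "O2'",
    Ph = "OP1",
    Rb = c("O2'", "O3'"),
    stop("unknown nt annotation: ", annotation))
}

.aaMemberSpec <- function(res = "ARG", portion = "s", atoms = NULL) {
  res <- toupper(res)
  if (!res %in% AMINO_ACIDS_3L) stop("not a canonical amino acid: ", res)
  if (is.null(atoms)) {
    side <- .DEFAULT_SIDE_ATOM[res]
    if (portion %in% c("s", "ms") && is.na(side))
      stop(res, " has no hydrogen-bonding side-chain atom")
    atoms <- switch(portion, m = "O", s = unname(side),
                    ms = c("O", unname(side)),
                    stop("portion must be m, s or ms"))
  }
  list(res = res, portion = portion, atoms = canonicalAtomName(atoms))
}

.ntMemberSpec <- function(res = "A", annotation = "WC", atoms = NULL,
                          tilt = NULL, expectedEdge = NULL) {
  res <- sub("^r", "", res)
  if (!res %in% RIBONUCLEOTIDES)
    stop("not a canonical ribonucleotide: ", res)
  if (is.null(atoms)) atoms <- .DEFAULT_NT_ATOMS(res, annotation)
  atoms <- canonicalAtomName(atoms)
  key <- paste(res, atoms[1])
  if (!is.null(tilt)) {
    rule <- .AMBIG_GEOM[[key]]
    if (is.null(rule) || length(atoms) != 1)
      stop("tilt applies to single ambiguous atoms only (got ", key, ")")
    ## strictly nearer first-listed adjacent atom -> first edge; the
    ## tie (tilt == 0) falls to the second-listed edge
    expectedEdge <- if (tilt > 0) rule$edge[1] else rule$edge[2]
    annotation <- expectedEdge
  }
  if (is.null(expectedEdge))
    expectedEdge <- if (annotation %in% c("WC", "HG", "SG")) annotation
                    else "NONE"
  list(res = res, annotation = annotation, atoms = atoms, tilt = tilt,
       expectedEdge = expectedEdge)
}

#' Specify one water bridge for the fixture generator
#'
#' Builds the specification of a single bridge: its topology
#' (`"A1:w:N1"` ... ; a `"cyc-"` prefix or `cyclic = TRUE` requests a
#' direct member-member hydrogen bond closing the cycle), the amino-acid
#' members (residue, portion `m`/`s`/`ms`, optionally explicit contact
#' atoms) and the ribonucleotide members (residue plus either an
#' annotation `WC`/`HG`/`SG`/`Ph`/`Rb` with default contact atoms,
#' explicit `atoms` with an `expectedEdge`, or a signed `tilt` in
#' Angstrom displacing the water along the adjacent-atom axis of an
#' ambiguous single atom). Unspecified members are filled from a
#' deterministic default cycle.
#'
#' @param topology e.g. `"A2:w:N1"`.
#' @param cyclic logical.
#' @param aa list of lists `(res, portion, atoms)`.
#' @param nt list of lists `(res, annotation, atoms, tilt, expectedEdge)`.
#' @param waterB B-factor for the bridging water (`NA`: drawn by
#'   [fixtureManifest()]).
#' @return a bridge specification list.
#' @examples
#' bridgeSpec("A1:w:N1", aa = list(list(res = "ARG", portion = "s")),
#'            nt = list(list(res = "A", annotation = "SG")))
#' @export
bridgeSpec <- function(topology = "A1:w:N1", cyclic = FALSE, aa = NULL,
                       nt = NULL, waterB = NA_real_) {
  if (startsWith(topology, "cyc-")) {
    cyclic <- TRUE
    topology <- substring(topology, 5)
  }
  m <- regexec("^A([0-9]+):w:N([0-9]+)$", topology)[[1]]
  if (m[1] < 0) stop("bad topology label: ", topology)
  g <- regmatches(topology, regexec("^A([0-9]+):w:N([0-9]+)$", topology))[[1]]
  nA <- as.integer(g[2]); nN <- as.integer(g[3])
  if (nA < 1 || nN < 1) stop("a bridge needs >=1 aa and >=1 nt member")
  if (nA + nN > 6)
    stop("requested ", nA + nN + 1,
         "-membered water coordination is infeasible (at most 6 ",
         "hydrogen-bond partners around one water)")
  aaDefaults <- list(list(res = "ARG", portion = "s"),
                     list(res = "SER", portion = "m"),
                     list(res = "ASN", portion = "s"),
                     list(res = "LYS", portion = "s"),
                     list(res = "THR", portion = "m"))
  ntDefaults <- list(list(res = "A", annotation = "WC"),
                     list(res = "G", annotation = "HG"),
                     list(res = "U", annotation = "WC"),
                     list(res = "C", annotation = "WC"),
                     list(res = "G", annotation = "SG"))
  if (is.null(aa)) aa <- aaDefaults[seq_len(nA)]
  if (is.null(nt)) nt <- ntDefaults[seq_len(nN)]
  if (length(aa) != nA || length(nt) != nN)
    stop("member lists do not match topology ", topology)
  aa <- lapply(aa, function(s) do.call(.aaMemberSpec, s))
  nt <- lapply(nt, function(s) do.call(.ntMemberSpec, s))
  list(topology = paste0("A", nA, ":w:N", nN), cyclic = cyclic, aa = aa,
       nt = nt, waterB = waterB)
}

#' Build a fixture manifest
#'
#' Validates bridge specifications, assigns seeded B-factors to entries
#' lacking one (bridging waters around 36, decoy waters around 45,
#' echoing the observation that bridging waters are more ordered than
#' bulk waters), and fixes the decoy content: non-bridging waters (the
#' first bonded to a lone Ser, the rest isolated) and within-class
#' decoy bonds (a protein-protein and an RNA-RNA hydrogen-bonded pair)
#' that must not become bridges.
#'
#' @param entries list of [bridgeSpec()] outputs.
#' @param seed integer seed; the manifest fully determines the fixture.
#' @param decoyWaters number of non-bridging waters.
#' @param decoyBonds number of within-class bonded residue pairs (0-2).
#' @return a `fixtureManifest` list.
#' @export
fixtureManifest <- function(entries, seed = 1L, decoyWaters = 5L,
                            decoyBonds = 2L) {
  stopifnot(is.list(entries), length(entries) >= 1)
  set.seed(as.integer(seed))
  for (i in seq_along(entries)) {
    if (is.na(entries[[i]]$waterB))
      entries[[i]]$waterB <- round(pmin(80, pmax(5,
        stats::rnorm(1, 36, 5))), 2)
  }
  decoyB <- round(pmin(90, pmax(5, stats::rnorm(decoyWaters, 45, 5))), 2)
  out <- list(entries = entries, seed = as.integer(seed),
              decoyWaters = as.integer(decoyWaters),
              decoyBonds = min(2L, as.integer(decoyBonds)),
              decoyWaterB = decoyB)
  class(out) <- "fixtureManifest"
  out
}

## Minimum distance from a candidate water position to the residue's
## polar atoms other than the contact atoms.
.vClearance <- function(tmpl, resname, atoms, v) {
  pol <- setdiff(names(.tmplPolar(resname)), atoms)
  if (!length(pol)) return(Inf)
  min(sqrt(rowSums(sweep(tmpl[pol, , drop = FALSE], 2, v)^2)))
}

## Water position (template frame) for a contact of 1 or 2 atoms.
## The placement direction is searched deterministically so that every
## non-contact polar atom of the residue stays >= 3.55 A from the
## water (detection cutoff + 0.2 A margin); for ambiguous single atoms
## the search axis is the adjacent-atom axis, which preserves the
## requested distance-rule ordering (and the exact tie at tilt 0).
.contactFrame <- function(tmpl, resname, atoms, tilt = NULL) {
  coord <- function(a) tmpl[a, ]
  outward <- function(a) {
    nb <- intersect(atomNeighbours(resname, a), rownames(tmpl))
    if (!length(nb))
      stop("no neighbour geometry for ", resname, " ", a)
    .unit(coord(a) - colMeans(tmpl[nb, , drop = FALSE]))
  }
  anyPerp <- function(u) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    .unit(ref - sum(ref * u) * u)
  }
  searchAngles <- as.vector(rbind(seq(0, 180, by = 10),
                                  -seq(0, 180, by = 10)))

  if (length(atoms) == 1) {
    a <- atoms
    ct <- coord(a)
    dir0 <- outward(a)
    isAmb <- !is.null(tilt)
    axis12 <- NULL
    if (isAmb) {
      rule <- .AMBIG_GEOM[[paste(sub("^r", "", resname), a)]]
      axis12 <- .unit(coord(rule$adj[1]) - coord(rule$adj[2]))
    }
    mkV <- function(dir) {
      d <- if (isAmb && tilt != 0) .unit(2.8 * dir + tilt * axis12)
           else dir
      ct + 2.8 * d
    }
    axes <- if (isAmb) list(axis12)
            else list(anyPerp(dir0), .unit(crossprod3(dir0, anyPerp(dir0))))
    for (ax in axes) for (ang in searchAngles) {
      dir <- if (ang == 0) dir0
             else as.vector(.rotAxis(ax, ang * pi / 180) %*% dir0)
      v <- mkV(dir)
      if (.vClearance(tmpl, resname, atoms, v) >= 3.55)
        return(list(v = v, centre = ct))
    }
    stop("no clear water placement for ", resname, " ",
         paste(atoms, collapse = "/"))
  }

  c1 <- coord(atoms[1]); c2 <- coord(atoms[2])
  sep <- sqrt(sum((c2 - c1)^2))
  if (sep >= 2 * 2.85)
    stop("atoms ", paste(atoms, collapse = "/"), " of ", resname,
         " are too far apart (", round(sep, 2),
         " A) for a shared water contact")
  mid <- (c1 + c2) / 2
  axis <- .unit(c2 - c1)
  o <- outward(atoms[1]) + outward(atoms[2])
  perp <- o - sum(o * axis) * axis
  if (sqrt(sum(perp^2)) < 1e-6) perp <- anyPerp(axis)
  perp <- .unit(perp)
  h <- sqrt(2.85^2 - (sep / 2)^2)
  for (ang in searchAngles) {
    p <- if (ang == 0) perp
         else as.vector(.rotAxis(axis, ang * pi / 180) %*% perp)
    v <- mid + h * p
    if (.vClearance(tmpl, resname, atoms, v) >= 3.55)
      return(list(v = v, centre = mid))
  }
  stop("no clear water placement for ", resname, " ",
       paste(atoms, collapse = "/"))
}

crossprod3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## Rigid placement: water lands on W, contact direction along -slotDir,
## free spin about the contact axis.
.placeMember <- function(tmpl, frame, slotDir, W, spin = 0) {
  R1 <- .rotBetween(frame$v - frame$centre, -slotDir)
  R <- if (spin != 0) .rotAxis(-slotDir, spin) %*% R1 else R1
  out <- sweep(tmpl, 2, frame$v) %*% t(R)
  sweep(out, 2, W, `+`)
}

.SLOT_DIRS <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))

## Direct-bond candidate atoms (excluding water-contact atoms), in
## deterministic preference order.
.directCandidates <- function(aaSpec, ntSpec) {
  aaRoles <- donorAcceptorRoles(aaSpec$res)
  ntRoles <- donorAcceptorRoles(ntSpec$res)
  aaFree <- setdiff(intersect(names(aaRoles),
                              rownames(residueTemplate(aaSpec$res))),
                    aaSpec$atoms)
  ntFree <- setdiff(intersect(names(ntRoles),
                              rownames(residueTemplate(ntSpec$res))),
                    ntSpec$atoms)
  cand <- list()
  for (aaAtom in aaFree) for (ntAtom in ntFree) {
    ar <- aaRoles[[aaAtom]]; nr <- ntRoles[[ntAtom]]
    if ((ar %in% c("donor", "both") && nr %in% c("acceptor", "both")) ||
        (nr %in% c("donor", "both") && ar %in% c("acceptor", "both")))
      cand[[length(cand) + 1]] <- c(aaAtom, ntAtom)
  }
  cand
}

## Polar atoms (name -> role) of a template residue, for validation.
.tmplPolar <- function(resname) {
  roles <- donorAcceptorRoles(resname)
  roles[names(roles) %in% rownames(residueTemplate(resname))]
}

#' Generate a synthetic PDB fixture from a manifest
#'
#' Realizes every requested bridge with idealized residue templates on
#' a 30 Angstrom grid, validates that the intended hydrogen bonds (and
#' only those) satisfy the default criteria with margin, writes the
#' structure as PDB, and returns the expected pipeline output derived
#' from the manifest alone: per-bridge labels, cyclic flags, expected
#' systematic names, per-contact expected edges/moieties, bond-level
#' expectation tables and water B-factors.
#'
#' @param manifest a [fixtureManifest()].
#' @param path output PDB path.
#' @return list with `path`, `structure` (the assembled
#'   [RnpStructure-class]), `bridges`, `ntEdges`, `aaPortions`,
#'   `aaBonds`, `ntBonds` data.frames and `counts` (water totals and
#'   expected B-factor means).
#' @export
generateFixture <- function(manifest, path) {
  stopifnot(inherits(manifest, "fixtureManifest"))
  entries <- manifest$entries
  nE <- length(entries)
  cellW <- function(i) c(30 * ((i - 1) %% 8), 30 * ((i - 1) %/% 8), 0)

  atomRows <- list()
  aaCounter <- 0L; ntCounter <- 0L
  addResidue <- function(chain, resno, resname, coords, b = 20) {
    atomRows[[length(atomRows) + 1]] <<- data.frame(
      chain = chain, resno = resno, resname = resname,
      atom = rownames(coords), x = coords[, 1], y = coords[, 2],
      z = coords[, 3], b = b, stringsAsFactors = FALSE)
  }

  expBridges <- list(); expEdges <- list(); expPortions <- list()
  expAaBonds <- list(); expNtBonds <- list()
  intended <- list()     # intended H-bond atom pairs (resid, atom) x2

  for (i in seq_len(nE)) {
    e <- entries[[i]]
    W <- cellW(i)
    waterRes <- sprintf("W/%d/HOH", i)
    addResidue("W", i, "HOH",
               matrix(W, 1, dimnames = list("O", NULL)), b = e$waterB)

    members <- c(lapply(e$aa, function(s) c(s, list(kind = "aa"))),
                 lapply(e$nt, function(s) c(s, list(kind = "nt"))))
    nA0 <- length(e$aa); nN0 <- length(e$nt)

    ## residue identities and contact frames are slot-independent
    meta <- vector("list", length(members))
    for (k in seq_along(members)) {
      s <- members[[k]]
      if (s$kind == "aa") {
        aaCounter <- aaCounter + 1L
        chain <- "A"; resno <- aaCounter * 10L
      } else {
        ntCounter <- ntCounter + 1L
        chain <- "B"; resno <- ntCounter * 10L
      }
      tmpl <- residueTemplate(s$res)
      frame <- .contactFrame(tmpl, s$res, s$atoms, s$tilt)
      ## water clearance from the member's own non-contact polar atoms
      ## (independent of placement)
      if (.vClearance(tmpl, s$res, s$atoms, frame$v) < 3.55)
        stop("infeasible fixture entry ", i, ": water too close to ",
             s$res, " atoms")
      meta[[k]] <- list(spec = s, chain = chain, resno = resno,
                        resname = s$res, frame = frame,
                        resid = sprintf("%s/%d/%s", chain, resno, s$res))
      for (at in s$atoms)
        intended[[length(intended) + 1]] <-
          c(waterRes, "O", meta[[k]]$resid, at)
    }

    ## one placement attempt for a given member -> slot assignment;
    ## returns placed coordinates + any direct-bond pairs, or errors
    attemptPlacement <- function(slotIdx) {
      slotDir <- function(k) .SLOT_DIRS[slotIdx[k], ]
      placed <- vector("list", length(members))
      for (k in seq_along(members))
        placed[[k]] <- .placeMember(residueTemplate(meta[[k]]$resname),
                                    meta[[k]]$frame, slotDir(k), W)
      polarOf <- function(k) {
        r <- .tmplPolar(meta[[k]]$resname)
        list(names = names(r), xyz = placed[[k]][names(r), , drop = FALSE],
             roles = unname(r))
      }
      compatible <- function(r1, r2)
        (r1 %in% c("donor", "both") && r2 %in% c("acceptor", "both")) ||
        (r2 %in% c("donor", "both") && r1 %in% c("acceptor", "both"))
      clashScore <- function(k1, k2) {
        p1 <- polarOf(k1); p2 <- polarOf(k2)
        d <- .crossDist(p1$xyz, p2$xyz)
        d[!.compatMat(p1$roles, p2$roles)] <- Inf
        min(d, Inf)
      }
      spinTo <- function(k, spin)
        .placeMember(residueTemplate(meta[[k]]$resname), meta[[k]]$frame,
                     slotDir(k), W, spin)
      clearOf <- function(k)
        min(vapply(seq_along(members)[-k], function(kk)
          clashScore(kk, k), numeric(1)), Inf)

      ## spin selection: forward-greedy (bulkiest first), then
      ## coordinate-ascent sweeps until every inter-member polar pair
      ## clears the guard band
      if (length(members) > 1) {
        allClear <- function()
          all(vapply(seq_along(members), function(k)
            clearOf(k) >= 3.55, logical(1)))
        sizeOf <- vapply(members, function(s)
          nrow(residueTemplate(s$res)), integer(1))
        ord <- order(-sizeOf)
        bestSpinAgainst <- function(k, against) {
          best <- -Inf; bestSpin <- 0
          for (spin in seq(0, 350, by = 10) * pi / 180) {
            placed[[k]] <<- spinTo(k, spin)
            sc <- if (length(against))
              min(vapply(against, function(kk) clashScore(kk, k),
                         numeric(1)))
            else Inf
            if (sc > best) { best <- sc; bestSpin <- spin }
          }
          placed[[k]] <<- spinTo(k, bestSpin)
          best
        }
        for (j in seq_along(ord))
          bestSpinAgainst(ord[j], ord[seq_len(j - 1)])
        done <- FALSE
        for (sweep in 1:4) {
          if (allClear()) { done <- TRUE; break }
          for (k in seq_along(members))
            bestSpinAgainst(k, seq_along(members)[-k])
        }
        if (!done && !allClear())
          stop("cannot separate the members by spinning")
      }

      ## cyclic entries: joint spin search bringing one direct-bond
      ## pair to hydrogen-bond distance while keeping all else apart
      direct <- list()
      if (e$cyclic) {
        combos <- expand.grid(k1 = seq_along(e$aa),
                              k2 = length(e$aa) + seq_along(e$nt))
        combos <- combos[order(-apply(combos, 1, function(r)
          sum(slotDir(r[1]) * slotDir(r[2])))), , drop = FALSE]
        spins <- seq(0, 345, by = 15) * pi / 180
        success <- NULL
        for (ci in seq_len(nrow(combos))) {
          k1 <- combos$k1[ci]; k2 <- combos$k2[ci]
          cands <- .directCandidates(members[[k1]], members[[k2]])
          if (!length(cands)) next
          r1 <- .tmplPolar(meta[[k1]]$resname)
          r2 <- .tmplPolar(meta[[k2]]$resname)
          compat <- .compatMat(unname(r1), unname(r2))
          candIdx <- vapply(cands, function(cn)
            c(match(cn[1], names(r1)), match(cn[2], names(r2))),
            integer(2))
          spun1 <- lapply(spins, function(s)
            spinTo(k1, s)[names(r1), , drop = FALSE])
          spun2 <- lapply(spins, function(s)
            spinTo(k2, s)[names(r2), , drop = FALSE])
          for (a1 in seq_along(spins)) {
            for (a2 in seq_along(spins)) {
              d <- .crossDist(spun1[[a1]], spun2[[a2]])
              dc <- d
              dc[!compat] <- Inf
              ## primary bond in range; every other compatible pair is
              ## either a clean additional bond (<= 3.10) or clearly
              ## apart (>= 3.55): nothing in the ambiguous band
              if (any(dc > 3.10 & dc < 3.55)) next
              prim <- dc[t(candIdx)]
              hit <- which(prim >= 2.75 & prim <= 3.10)
              if (!length(hit)) next
              placed[[k1]] <- spinTo(k1, spins[a1])
              placed[[k2]] <- spinTo(k2, spins[a2])
              okRest <- all(vapply(seq_along(members), function(kk) {
                if (kk %in% c(k1, k2)) return(TRUE)
                clashScore(kk, k1) >= 3.55 && clashScore(kk, k2) >= 3.55
              }, logical(1)))
              if (!okRest) next
              bonded <- which(dc <= 3.10, arr.ind = TRUE)
              success <- lapply(seq_len(nrow(bonded)), function(rr)
                list(a = names(r1)[bonded[rr, 1]],
                     b = names(r2)[bonded[rr, 2]]))
              break
            }
            if (!is.null(success)) break
          }
          if (!is.null(success)) break
        }
        if (is.null(success))
          stop("cannot realize direct bond")
        for (p in success)
          direct[[length(direct) + 1]] <-
            c(meta[[k1]]$resid, p$a, meta[[k2]]$resid, p$b)
      }
      list(placed = placed, direct = direct)
    }

    ## slot allocation: nucleotides are bulky and take mutually
    ## opposed/spread directions first, amino acids fill the rest;
    ## when an allocation is infeasible the nucleotide slots are
    ## permuted before giving up
    ntPerms <- .slotPermutations(nN0)
    res <- NULL
    for (pi in seq_len(nrow(ntPerms))) {
      ntSlots <- ntPerms[pi, ]
      aaSlots <- setdiff(c(2L, 4L, 6L, 5L, 3L, 1L), ntSlots)[seq_len(nA0)]
      res <- tryCatch(attemptPlacement(c(aaSlots, ntSlots)),
                      error = function(err) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("infeasible fixture entry ", i, " (", e$topology,
           "): no valid member arrangement found")
    placed <- res$placed
    for (p in res$direct) intended[[length(intended) + 1]] <- p

    for (k in seq_along(members))
      addResidue(meta[[k]]$chain, meta[[k]]$resno, meta[[k]]$resname,
                 placed[[k]])

    ## expected inventory for this entry
    nA <- length(e$aa); nN <- length(e$nt)
    aaTerms <- data.frame(
      name = vapply(e$aa, function(s) .titleCase(s$res), character(1)),
      portion = vapply(e$aa, `[[`, character(1), "portion"),
      tie = vapply(seq_len(nA), function(k) meta[[k]]$resid,
                   character(1)), stringsAsFactors = FALSE)
    ntTerms <- data.frame(
      name = vapply(e$nt, function(s) unname(NT_DISPLAY[s$res]),
                    character(1)),
      annotation = vapply(e$nt, `[[`, character(1), "annotation"),
      tie = vapply(seq_len(nN), function(k) meta[[nA + k]]$resid,
                   character(1)), stringsAsFactors = FALSE)
    nBonds <- sum(vapply(members, function(s) length(s$atoms), integer(1)))
    expBridges[[i]] <- data.frame(
      water = waterRes,
      label = paste0(if (e$cyclic) "cyc-" else "", e$topology),
      topo = e$topology, cyclic = e$cyclic, order = nA + nN + 1L,
      name = .expectedName(aaTerms, ntTerms, e$cyclic),
      waterB = e$waterB, overTetrahedral = nBonds > 4,
      nBonds = nBonds, stringsAsFactors = FALSE)
    for (k in seq_len(nN)) {
      s <- e$nt[[k]]; mt <- meta[[nA + k]]
      expEdges[[length(expEdges) + 1]] <- data.frame(
        water = waterRes, nt = mt$resid, resname = s$res,
        annotation = s$annotation, edge = s$expectedEdge,
        moiety = if (identical(sort(s$atoms), sort(c("O2'", "O3'"))) ||
                     identical(s$atoms, "O2'")) "Rb"
                 else if (s$annotation == "Ph") "Ph"
                 else if (s$annotation == "Rb") "Rb" else "Nb",
        stringsAsFactors = FALSE)
      for (at in s$atoms)
        expNtBonds[[length(expNtBonds) + 1]] <- data.frame(
          water = waterRes, resid = mt$resid, resname = s$res, atom = at,
          stringsAsFactors = FALSE)
    }
    for (k in seq_len(nA)) {
      s <- e$aa[[k]]; mt <- meta[[k]]
      expPortions[[length(expPortions) + 1]] <- data.frame(
        water = waterRes, aa = mt$resid, portion = s$portion,
        stringsAsFactors = FALSE)
      for (at in s$atoms)
        expAaBonds[[length(expAaBonds) + 1]] <- data.frame(
          water = waterRes, resid = mt$resid, resname = s$res, atom = at,
          stringsAsFactors = FALSE)
    }
  }

  ## decoy waters: first one hydrogen-bonded to a lone serine (still
  ## non-bridging), the rest isolated
  cell <- nE
  for (d in seq_len(manifest$decoyWaters)) {
    cell <- cell + 1L
    W <- cellW(cell)
    wResno <- nE + d
    addResidue("W", wResno, "HOH",
               matrix(W, 1, dimnames = list("O", NULL)),
               b = manifest$decoyWaterB[d])
    if (d == 1L) {
      aaCounter <- aaCounter + 1L
      tmpl <- residueTemplate("SER")
      frame <- .contactFrame(tmpl, "SER", "OG")
      addResidue("A", aaCounter * 10L, "SER",
                 .placeMember(tmpl, frame, .SLOT_DIRS[1, ], W))
      intended[[length(intended) + 1]] <-
        c(sprintf("W/%d/HOH", wResno), "O",
          sprintf("A/%d/SER", aaCounter * 10L), "OG")
    }
  }

  ## decoy within-class bonds: protein-protein, then RNA-RNA
  ## a direct residue-residue contact is laid out with two reference
  ## points 2.9 A apart: each member's contact atom lands on its point
  ## with the residue body extending away from the other member
  addDecoyPair <- function(W, res1, atom1, chainId1, no1, res2, atom2,
                           chainId2, no2) {
    sep <- 2.9
    t1 <- residueTemplate(res1); f1 <- .contactFrame(t1, res1, atom1)
    addResidue(chainId1, no1, res1,
               .placeMember(t1, f1, c(-1, 0, 0), W + c(2.8, 0, 0)))
    t2 <- residueTemplate(res2); f2 <- .contactFrame(t2, res2, atom2)
    addResidue(chainId2, no2, res2,
               .placeMember(t2, f2, c(1, 0, 0), W + c(sep - 2.8, 0, 0)))
    intended[[length(intended) + 1]] <<-
      c(sprintf("%s/%d/%s", chainId1, no1, res1), atom1,
        sprintf("%s/%d/%s", chainId2, no2, res2), atom2)
  }
  if (manifest$decoyBonds >= 1L) {
    cell <- cell + 1L
    aaCounter <- aaCounter + 2L
    addDecoyPair(cellW(cell), "SER", "OG", "A", (aaCounter - 1L) * 10L,
                 "ASN", "OD1", "A", aaCounter * 10L)
  }
  if (manifest$decoyBonds >= 2L) {
    cell <- cell + 1L
    ntCounter <- ntCounter + 2L
    addDecoyPair(cellW(cell), "G", "N2", "B", (ntCounter - 1L) * 10L,
                 "U", "O4", "B", ntCounter * 10L)
  }

  all <- do.call(rbind, atomRows)
  structure <- structureFromAtoms(
    chain = all$chain, resno = all$resno, resname = all$resname,
    atom = all$atom, x = all$x, y = all$y, z = all$z, b = all$b,
    pdbIdentifier = sub("\\.pdb$", "", basename(path)))
  .validateFixture(structure, intended)
  writeStructurePDB(structure, path)

  expB <- do.call(rbind, expBridges)
  counts <- list(
    nWaters = nE + manifest$decoyWaters,
    nBridgingWaters = nE,
    meanBBridging = mean(expB$waterB),
    meanBAll = mean(c(expB$waterB,
                      manifest$decoyWaterB[seq_len(manifest$decoyWaters)])))
  list(path = path, structure = structure, manifest = manifest,
       bridges = expB, ntEdges = do.call(rbind, expEdges),
       aaPortions = do.call(rbind, expPortions),
       aaBonds = do.call(rbind, expAaBonds),
       ntBonds = do.call(rbind, expNtBonds), counts = counts)
}

## Assert that exactly the intended donor/acceptor contacts fall within
## the detection cutoff, with a 0.2 A guard band around it.
.validateFixture <- function(structure, intended) {
  pol <- .polarAtoms(structure)
  pr <- .neighbourPairs(as.matrix(pol[, c("x", "y", "z")]), 3.55)
  key <- function(r1, a1, r2, a2)
    paste(sort(c(paste(r1, a1), paste(r2, a2))), collapse = " | ")
  want <- vapply(intended, function(p) key(p[1], p[2], p[3], p[4]),
                 character(1))
  got <- character(0)
  if (nrow(pr)) for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]; j <- pr[r, 2]
    if (pol$resid[i] == pol$resid[j]) next
    if (pol$resclass[i] == "WATER" && pol$resclass[j] == "WATER") next
    ri <- pol$role[i]; rj <- pol$role[j]
    ok <- (ri %in% c("donor", "both") && rj %in% c("acceptor", "both")) ||
          (rj %in% c("donor", "both") && ri %in% c("acceptor", "both"))
    if (!ok) next
    got <- c(got, key(pol$resid[i], pol$atom[i], pol$resid[j],
                      pol$atom[j]))
  }
  got <- unique(got)
  extra <- setdiff(got, want)
  missing <- setdiff(want, got)
  if (length(extra) || length(missing))
    stop("fixture validation failed;\n  unintended contacts: ",
         paste(extra, collapse = "; "), "\n  missing contacts: ",
         paste(missing, collapse = "; "))
  invisible(TRUE)
}

#' Generate a single-nucleotide edge probe
#'
#' Writes a mini-PDB with one ribonucleotide and one water placed
#' 2.8 Angstrom from an ambiguous single atom, displaced by
#' `displacement` Angstrom along the axis joining the two adjacent
#' atoms (positive: toward the first-listed adjacent atom, whose edge
#' the distance rule then selects; zero: exact tie, which falls to the
#' second-listed edge).
#'
#' @param ntName ribonucleotide (`"rA"`, `"A"`, ...).
#' @param targetAtom an ambiguous atom (`N6`, `O6`, `N2`, `O2`).
#' @param displacement signed Angstrom.
#' @param path output PDB path.
#' @return list with `path`, `expectedEdge`, `nt` and `water` residue
#'   keys, and `intAtom`.
#' @examples
#' generateEdgeProbe("rA", "N6", +0.8, tempfile(fileext = ".pdb"))$expectedEdge
#' @export
generateEdgeProbe <- function(ntName, targetAtom, displacement, path) {
  res <- toupper(sub("^r", "", ntName))
  targetAtom <- canonicalAtomName(targetAtom)
  rule <- .AMBIG_GEOM[[paste(res, targetAtom)]]
  if (is.null(rule))
    stop(res, " ", targetAtom, " is not an ambiguous single atom")
  tmpl <- residueTemplate(res)
  frame <- .contactFrame(tmpl, res, targetAtom,
                         tilt = if (displacement != 0) displacement
                                else NULL)
  W <- frame$v
  ## expectation computed at PDB file precision (3 decimals), so an
  ## exact displacement-0 tie stays a tie after serialization
  d1 <- sqrt(sum((round(tmpl[rule$adj[1], ], 3) - round(W, 3))^2))
  d2 <- sqrt(sum((round(tmpl[rule$adj[2], ], 3) - round(W, 3))^2))
  expectedEdge <- if (d1 < d2) rule$edge[1] else rule$edge[2]
  atomRows <- rbind(
    data.frame(chain = "B", resno = 10L, resname = res,
               atom = rownames(tmpl), x = tmpl[, 1], y = tmpl[, 2],
               z = tmpl[, 3], b = 20, stringsAsFactors = FALSE),
    data.frame(chain = "W", resno = 1L, resname = "HOH", atom = "O",
               x = W[1], y = W[2], z = W[3], b = 30,
               stringsAsFactors = FALSE))
  structure <- structureFromAtoms(
    chain = atomRows$chain, resno = atomRows$resno,
    resname = atomRows$resname, atom = atomRows$atom, x = atomRows$x,
    y = atomRows$y, z = atomRows$z, b = atomRows$b,
    pdbIdentifier = "edge_probe")
  .validateFixture(structure,
                   list(c("W/1/HOH", "O", sprintf("B/10/%s", res),
                          targetAtom)))
  writeStructurePDB(structure, path)
  list(path = path, expectedEdge = expectedEdge,
       nt = sprintf("B/10/%s", res), water = "W/1/HOH",
       intAtom = targetAtom, displacement = displacement)
}

## Independent assembly of the expected systematic name (the ordering
## rules re-implemented separately from renderName on purpose).
.expectedName <- function(aaTerms, ntTerms, cyclic) {
  ag <- match(aaTerms$portion, c("s", "ms", "m"))
  ao <- order(ag, -rank(aaTerms$name, ties.method = "first"), aaTerms$tie)
  ng <- match(ntTerms$annotation, c("WC", "HG", "SG", "Ph", "Rb"))
  no <- order(ng, ntTerms$name, ntTerms$tie)
  paste0(if (cyclic) "cyc-" else "",
         paste0(aaTerms$name[ao], "(", aaTerms$portion[ao], ")",
                collapse = "|"),
         ":w:",
         paste0(ntTerms$name[no], "(", ntTerms$annotation[no], ")",
                collapse = "|"))
}

#' Default test ensemble manifest
#'
#' A seeded ensemble covering every observed topology (triplet through
#' order-6, cyclic and acyclic), every realizable two-atom pair-list
#' case (pairs involving a glycosidic nitrogen cannot occur in water
#' hydrogen bonds and are excluded), both branches of every ambiguous
#' single-atom distance rule, unambiguous singles, an `ms` portion
#' contact, the `O2'`/`O3'` ribose rule, `O2'`-alone SG semantics,
#' phosphate contacts, an over-tetrahedral water, the three worked
#' nomenclature examples, plus decoy waters and within-class decoy
#' bonds.
#'
#' @param seed integer seed.
#' @return a [fixtureManifest()].
#' @export
defaultEnsembleManifest <- function(seed = 1L) {
  e <- list()
  add <- function(...) e[[length(e) + 1]] <<- bridgeSpec(...)

  ## all Figure-2-style topologies, acyclic and cyclic
  for (topo in c("A1:w:N1", "A2:w:N1", "A1:w:N2", "A3:w:N1", "A2:w:N2",
                 "A1:w:N3")) {
    add(topo)
    add(topo, cyclic = TRUE)
  }
  ## realizable two-atom pair-list cases
  pairCase <- function(res, atoms, edge)
    add("A1:w:N1", nt = list(list(res = res, atoms = atoms,
                                  annotation = edge,
                                  expectedEdge = edge)))
  pairCase("A", c("N1", "N6"), "WC")
  pairCase("A", c("N6", "N7"), "HG")
  pairCase("A", c("N3", "O2'"), "SG")
  pairCase("G", c("N1", "N2"), "WC")
  pairCase("G", c("N1", "O6"), "WC")
  pairCase("G", c("N7", "O6"), "HG")
  pairCase("G", c("N2", "N3"), "SG")
  pairCase("G", c("N3", "O2'"), "SG")
  pairCase("C", c("N3", "N4"), "WC")
  pairCase("C", c("N3", "O2"), "WC")
  pairCase("C", c("O2", "O2'"), "SG")
  pairCase("U", c("N3", "O2"), "WC")
  pairCase("U", c("N3", "O4"), "WC")
  pairCase("U", c("O2", "O2'"), "SG")
  ## ambiguous singles, both branches of the distance rule
  for (tl in c(+0.8, -0.8)) {
    add("A1:w:N1", nt = list(list(res = "A", atoms = "N6", tilt = tl)))
    add("A1:w:N1", nt = list(list(res = "G", atoms = "O6", tilt = tl)))
    add("A1:w:N1", nt = list(list(res = "G", atoms = "N2", tilt = tl)))
    add("A1:w:N1", nt = list(list(res = "C", atoms = "O2", tilt = tl)))
    add("A1:w:N1", nt = list(list(res = "U", atoms = "O2", tilt = tl)))
  }
  ## ms portion, ribose rule, phosphate, O2'-alone, over-tetrahedral
  add("A1:w:N1", aa = list(list(res = "THR", portion = "ms")))
  add("A1:w:N1", nt = list(list(res = "G", annotation = "Rb")))
  add("A1:w:N1", aa = list(list(res = "SER", portion = "m")),
      nt = list(list(res = "U", annotation = "Ph")))
  add("A1:w:N1", aa = list(list(res = "LYS", portion = "s")),
      nt = list(list(res = "C", annotation = "SG")))
  add("A3:w:N2")
  ## worked nomenclature examples
  add("A3:w:N1",
      aa = list(list(res = "TYR", portion = "s"),
                list(res = "SER", portion = "m"),
                list(res = "ALA", portion = "m")),
      nt = list(list(res = "A", annotation = "HG")))
  add("A2:w:N3", cyclic = TRUE,
      aa = list(list(res = "THR", portion = "s"),
                list(res = "GLY", portion = "m")),
      nt = list(list(res = "U", annotation = "Ph"),
                list(res = "C", annotation = "Rb"),
                list(res = "G", annotation = "Rb")))
  add("A1:w:N1", aa = list(list(res = "ARG", portion = "s")),
      nt = list(list(res = "A", annotation = "SG")))
  add("A1:w:N1", cyclic = TRUE,
      aa = list(list(res = "GLU", portion = "s")),
      nt = list(list(res = "G", annotation = "WC")))

  fixtureManifest(e, seed = seed, decoyWaters = 5L, decoyBonds = 2L)
}
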