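# Independent oracles and shared fixtures.
#
# bruteForceHBonds() re-derives the heavy-atom bond list by a plain
# all-pairs scan over the role tables; it shares no code with the
# cell-list detector it checks.

bruteForceHBonds <- function(structure, criteria = hbondCriteria()) {
  a <- atoms(structure)
  a <- a[a$resclass %in% c("AMINO_ACID", "RIBONUCLEOTIDE", "WATER"), ]
  role <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$resclass[i] == "WATER") {
      role[i] <- if (a$elem[i] == "O") "both" else "none"
    } else {
      tab <- donorAcceptorRoles(a$resname[i])
      role[i] <- if (a$atom[i] %in% names(tab)) tab[[a$atom[i]]] else "none"
    }
  }
  keep <- role != "none"
  a <- a[keep, ]; role <- role[keep]
  keys <- character(0)
  n <- nrow(a)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (a$resid[i] == a$resid[j]) next
    if (a$resclass[i] == "WATER" && a$resclass[j] == "WATER") next
    ok <- (role[i] %in% c("donor", "both") &&
             role[j] %in% c("acceptor", "both")) ||
      (role[j] %in% c("donor", "both") &&
         role[i] %in% c("acceptor", "both"))
    if (!ok) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    if (d > criteria@maxDA) next
    keys <- c(keys, paste(sort(c(paste(a$resid[i], a$atom[i]),
                                 paste(a$resid[j], a$atom[j]))),
                          collapse = " | "))
  }
  sort(unique(keys))
}

bondKeys <- function(bonds) {
  if (!nrow(bonds)) return(character(0))
  sort(apply(cbind(paste(bonds$don_resid, bonds$don_atom),
                   paste(bonds$acc_resid, bonds$acc_atom)), 1,
             function(r) paste(sort(r), collapse = " | ")))
}

# One shared seeded ensemble per test run (generation is the expensive
# step); memoized across test files.
.fixtureCache <- new.env(parent = emptyenv())

ensembleFixture <- function(seed = 20240915) {
  key <- paste0("s", seed)
  if (is.null(.fixtureCache[[key]])) {
    path <- file.path(tempdir(), sprintf("ensemble_%d.pdb", seed))
    fx <- generateFixture(defaultEnsembleManifest(seed = seed), path)
    s <- readStructure(path)
    set <- surveyStructure(s)
    inv <- annotateBridges(set, s)
    .fixtureCache[[key]] <- list(fx = fx, structure = s, set = set,
                                 inv = inv)
  }
  .fixtureCache[[key]]
}

# Minimal in-memory structure: one template residue plus a water oxygen
# at an arbitrary position.
residuePlusWater <- function(resname, waterXYZ, chain = "A",
                             resno = 1L, waterB = 30) {
  tp <- residueTemplate(resname)
  structureFromAtoms(
    chain = c(rep(chain, nrow(tp)), "W"),
    resno = c(rep(resno, nrow(tp)), 99L),
    resname = c(rep(sub("^r", "", toupper(resname)), nrow(tp)), "HOH"),
    atom = c(rownames(tp), "O"),
    x = c(tp[, 1], waterXYZ[1]), y = c(tp[, 2], waterXYZ[2]),
    z = c(tp[, 3], waterXYZ[3]),
    b = c(rep(20, nrow(tp)), waterB))
}
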