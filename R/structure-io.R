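## Reading and writing crystal structures. Parsing is delegated to
## bio3d (read.pdb / read.cif); this module normalizes atom naming,
## selects one model, resolves altlocs and classifies residues.

#' Canonicalize atom names
#'
#' Maps the common PDB atom-name dialects onto one canonical form:
#' `*` and the typographic prime U+2032 become the ASCII apostrophe
#' (`O2*`, `O2′` -> `O2'`), and the legacy phosphate names
#' `O1P`/`O2P`/`O3P` become `OP1`/`OP2`/`OP3`.
#'
#' @param atomName character vector of atom names.
#' @return character vector of canonical names.
#' @examples
#' canonicalAtomName(c("O2*", "O1P", "ND2"))
#' @export
canonicalAtomName <- function(atomName) {
  x <- trimws(atomName)
  x <- gsub("*", "'", x, fixed = TRUE)
  x <- gsub("′", "'", x, fixed = TRUE)
  legacy <- c(O1P = "OP1", O2P = "OP2", O3P = "OP3")
  hit <- x %in% names(legacy)
  x[hit] <- legacy[x[hit]]
  x
}

## Build the canonical atoms data.frame from bio3d-style vectors.
.buildAtomTable <- function(chain, resno, ins, resname, atom, elem,
                            x, y, z, b, occ, altloc,
                            waterNames = DEFAULT_WATER_NAMES) {
  chain <- ifelse(is.na(chain) | chain == "", "A", as.character(chain))
  ins <- ifelse(is.na(ins), "", as.character(ins))
  resname <- toupper(trimws(as.character(resname)))
  atom <- canonicalAtomName(atom)
  elem <- toupper(trimws(ifelse(is.na(elem), "", as.character(elem))))
  guess <- substr(sub("^[0-9]*", "", atom), 1, 1)
  elem[elem == ""] <- guess[elem == ""]
  b <- ifelse(is.na(b), 0, as.numeric(b))
  occ <- ifelse(is.na(occ), 1, as.numeric(occ))
  altloc <- ifelse(is.na(altloc), "", as.character(altloc))

  df <- data.frame(chain = chain, resno = as.integer(resno), ins = ins,
                   resname = resname,
                   resclass = classifyResidue(resname, waterNames),
                   resid = NA_character_, atom = atom, elem = elem,
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   b = b, occ = occ, altloc = altloc,
                   stringsAsFactors = FALSE)
  df$resid <- sprintf("%s/%d%s/%s", df$chain, df$resno, df$ins, df$resname)

  ## Drop hydrogens/deuteriums: geometry is evaluated on heavy atoms and
  ## hydrogen positions are re-derived where needed.
  df <- df[!(df$elem %in% c("H", "D")) & !grepl("^[0-9]*[HD]", df$atom), ]

  ## A residue named like water but lacking an oxygen atom is not water.
  if (nrow(df)) {
    wat <- df$resclass == "WATER"
    if (any(wat)) {
      hasO <- tapply(df$atom == "O" | df$elem == "O", df$resid, any)
      bad <- wat & !hasO[df$resid]
      df$resclass[bad] <- "OTHER"
    }
  }

  ## Altloc resolution: keep the highest-occupancy conformer per atom;
  ## ties go to the lexicographically first altloc.
  if (nrow(df)) {
    key <- paste(df$resid, df$atom)
    ord <- order(key, -df$occ, df$altloc)
    df <- df[ord, ]
    df <- df[!duplicated(paste(df$resid, df$atom)), ]
  }

  ## Deterministic order: chain, resno, ins, then input-independent atom
  ## order within the residue.
  df <- df[order(df$chain, df$resno, df$ins, df$atom), ]
  df$altloc <- NULL
  rownames(df) <- NULL
  df
}

#' Read a crystal structure
#'
#' Parses a PDB or mmCIF file (via bio3d), retains a single model,
#' resolves alternate locations to the highest-occupancy conformer,
#' canonicalizes atom names, drops hydrogens, and classifies every
#' residue as amino acid, ribonucleotide, water or other. A structure
#' with no waters is valid (it simply yields no bridges downstream).
#'
#' @param path file path.
#' @param fmt `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param model integer, which model to retain (default 1).
#' @param pdbIdentifier optional identifier; defaults to the file stem.
#' @param waterNames residue names treated as water.
#' @return an [RnpStructure-class].
#' @examples
#' mf <- fixtureManifest(list(bridgeSpec("A1:w:N1")), seed = 1)
#' f <- generateFixture(mf, tempfile(fileext = ".pdb"))
#' readStructure(f$path)
#' @export
readStructure <- function(path, fmt = c("auto", "pdb", "mmcif"), model = 1L,
                          pdbIdentifier = NULL,
                          waterNames = DEFAULT_WATER_NAMES) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (fmt == "pdb") bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                      verbose = FALSE)
    else bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", fmt, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  nModels <- max(1L, nrow(as.matrix(pdb$xyz)))
  model <- as.integer(model)
  if (model < 1L || model > nModels)
    stop("model ", model, " requested but file has ", nModels, " model(s)")
  xyz <- as.matrix(pdb$xyz)
  if (nrow(xyz) >= model) {
    co <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
    a$x <- co[, 1]; a$y <- co[, 2]; a$z <- co[, 3]
  }
  at <- .buildAtomTable(chain = a$chain, resno = a$resno, ins = a$insert,
                        resname = a$resid, atom = a$elety, elem = a$elesy,
                        x = a$x, y = a$y, z = a$z, b = a$b, occ = a$o,
                        altloc = a$alt, waterNames = waterNames)
  if (is.null(pdbIdentifier))
    pdbIdentifier <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path),
                         ignore.case = TRUE)
  new("RnpStructure", pdbId = pdbIdentifier, modelIndex = model, atoms = at,
      resolution = NA_real_)
}

#' Build a structure from an atom table
#'
#' Programmatic constructor used by the fixture generator and tests:
#' takes raw atom vectors, applies the same normalization as
#' [readStructure()] and returns an [RnpStructure-class].
#'
#' @param chain,resno,ins,resname,atom,elem,x,y,z,b,occ,altloc atom
#'   vectors (recycled where scalar).
#' @param pdbIdentifier identifier string.
#' @param waterNames residue names treated as water.
#' @return an [RnpStructure-class].
#' @export
structureFromAtoms <- function(chain, resno, resname, atom, x, y, z,
                               ins = "", elem = NA, b = 20, occ = 1,
                               altloc = "", pdbIdentifier = "synthetic",
                               waterNames = DEFAULT_WATER_NAMES) {
  n <- length(atom)
  at <- .buildAtomTable(chain = rep_len(chain, n), resno = rep_len(resno, n),
                        ins = rep_len(ins, n), resname = rep_len(resname, n),
                        atom = atom, elem = rep_len(elem, n),
                        x = x, y = y, z = z, b = rep_len(b, n),
                        occ = rep_len(occ, n), altloc = rep_len(altloc, n),
                        waterNames = waterNames)
  new("RnpStructure", pdbId = pdbIdentifier, modelIndex = 1L, atoms = at)
}

#' Write a structure as a canonical PDB file
#'
#' Writes the retained model back out as PDB (via bio3d::write.pdb);
#' re-reading the file reproduces the same residues, atoms and classes
#' (round-trip), which is how fixtures are persisted.
#'
#' @param structure an [RnpStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  a <- atoms(structure)
  het <- a$resclass %in% c("WATER", "OTHER")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   insert = ifelse(a$ins == "", NA, a$ins),
                   elety = a$atom, o = a$occ, b = a$b, elesy = a$elem)
  invisible(path)
}
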