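## PDB structure input/output. Reading goes through bio3d (the field's
## standard R package for PDB files); only the first NMR model of an
## ensemble is retained. Writing (used by the fixture generator) emits
## fixed-column single-model records deterministically.

#' Parse a PDB file into a ProteinStructure
#'
#' Multi-model (NMR ensemble) files are reduced to MODEL 1. Chains are
#' re-indexed 1..k in file order; residues are re-indexed 1-based in
#' sequence order per chain while the author numbering is kept in
#' `residue_seq`. Atom names are normalized to the trailing-digit
#' (PDB-v3/NMRStar) spelling where the residue type is standard.
#'
#' @param path Path to a PDB-format file.
#' @return A [ProteinStructure-class] object.
#' @export
parsePDB <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  nModels <- sum(grepl("^MODEL", lines))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no polymer atoms (ATOM records) in ", path)
  ## first model only: bio3d's $atom already holds model 1
  chain_ids <- at$chain
  chain_ids[is.na(chain_ids) | chain_ids == ""] <- " "
  chain_levels <- unique(chain_ids)
  chain_index <- match(chain_ids, chain_levels)

  res_key <- paste(chain_index, at$resno, ifelse(is.na(at$insert), "",
                                                 at$insert))
  residue_index <- integer(nrow(at))
  for (ci in unique(chain_index)) {
    sel <- chain_index == ci
    keys <- res_key[sel]
    residue_index[sel] <- match(keys, unique(keys))
  }

  elem <- at$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- vapply(at$elety[bad], .elementOf, character(1))
  elem <- trimws(toupper(elem))

  name <- toupper(trimws(at$elety))
  res3 <- toupper(at$resid)
  std <- res3 %in% .AA3
  name[std] <- mapply(function(r, n) {
    tryCatch(convertAtomName(r, n, to = "pdbv3"), error = function(e) n)
  }, res3[std], name[std])

  atoms <- data.frame(
    chain_id = chain_ids, chain_index = chain_index,
    residue_index = residue_index, residue_seq = at$resno,
    residue_type = res3, atom_name = name, element = elem,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)

  pdbId <- toupper(sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
  new("ProteinStructure", pdbId = pdbId, atoms = atoms,
      metadata = list(nModels = max(nModels, 1L), source = path))
}

#' Write a ProteinStructure to a PDB file
#'
#' Deterministic fixed-column writer (single model). Coordinates are
#' rounded to the format's 0.001 A precision.
#'
#' @param structure A [ProteinStructure-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  a <- atoms(structure)
  fmtName <- function(n) {
    if (nchar(n) >= 4L || grepl("^[0-9]", n)) sprintf("%-4s", n)
    else sprintf(" %-3s", n)
  }
  lines <- character(nrow(a) + 2L)
  for (i in seq_len(nrow(a))) {
    lines[i] <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000L, fmtName(a$atom_name[i]), a$residue_type[i],
      substr(a$chain_id[i], 1, 1), a$residue_seq[i] %% 10000L,
      a$x[i], a$y[i], a$z[i], 1, 0, a$element[i])
  }
  lines[nrow(a) + 1L] <- "TER"
  lines[nrow(a) + 2L] <- "END"
  writeLines(lines, path)
  invisible(path)
}
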