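## The experiment-to-structure mapping and its restriction filters.
## Type-1 filters act on the PDB<->shift-entry mapping (protein-only,
## perfect alignment, homology culling); the type-2 filter scores
## individual structures with a pluggable structure-quality scorer
## against an energy cutoff (default 1000 kJ/mol).

#' Read a PDB-to-accession mapping file
#'
#' Whitespace-separated two-column text (PDB id, shift-archive
#' accession); '#' starts a comment.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional literal text instead of a file.
#' @return data.frame with columns pdb_id, bmrb_id.
#' @export
readMapping <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n"))
  } else {
    if (!file.exists(path)) stop("cannot read mapping file: ", path)
    readLines(path, warn = FALSE)
  }
  lines <- sub("#.*$", "", lines)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 2L)
      stop("malformed mapping line ", i, ": '", lines[i],
           "' (need two columns)")
    out[[length(out) + 1L]] <- data.frame(pdb_id = toupper(tok[1]),
                                          bmrb_id = tok[2],
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(pdb_id = character(0), bmrb_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Keep only perfectly aligned mapping entries
#'
#' Retains exactly the entries whose sequence identity is 100 percent;
#' an alignment with any gap or mismatch cannot reach 100 under the
#' columns-based identity definition. Rejections are logged.
#'
#' @param entries data.frame with an `alignment_identity` column.
#' @param logger Optional function(character) receiving log lines.
#' @return The surviving subset of `entries`.
#' @export
filterPerfectAlignment <- function(entries, logger = NULL) {
  stopifnot("alignment_identity" %in% names(entries))
  keep <- !is.na(entries$alignment_identity) &
    entries$alignment_identity == 100
  if (!is.null(logger) && any(!keep))
    for (i in which(!keep))
      logger(sprintf("perfect-alignment filter: dropped %s (identity %.3f)",
                     entries$pdb_id[i], entries$alignment_identity[i]))
  entries[keep, , drop = FALSE]
}

#' Greedy homology culling
#'
#' Removes sequences until no retained pair has pairwise identity
#' above the cutoff. Culling is by iterative removal: while any
#' over-cutoff pair remains, the sequence in conflict with the most
#' others is dropped (ties: the shorter sequence, then the later one
#' in input order), so long sequences are preferentially retained and
#' the result is deterministic given the input order.
#'
#' @param sequences Named character vector of one-letter sequences.
#' @param cutoff Identity cutoff percentage in (0, 100\]; default 10.
#' @param logger Optional function(character).
#' @return Character vector of retained names (input order).
#' @export
cullHomologs <- function(sequences, cutoff = 10, logger = NULL) {
  stopifnot(cutoff > 0, cutoff <= 100)
  if (!length(sequences)) return(character(0))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1L):n) {
    id <- alignmentIdentity(sequences[[i]], sequences[[j]])
    conflict[i, j] <- conflict[j, i] <- id > cutoff
  }
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(conflict[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    ## drop the worst offender; prefer keeping longer sequences
    cand <- which(deg == max(deg))
    drop <- cand[order(nchar(sequences)[cand], -cand)][1]
    alive[drop] <- FALSE
    if (!is.null(logger))
      logger(sprintf("homology culling: dropped %s (%d conflict(s) above %.1f%%)",
                     names(sequences)[drop], max(deg), cutoff))
  }
  names(sequences)[alive]
}

#' Protein-only filter
#'
#' Drops a mapping entry when its entity metadata reports any
#' non-protein polymer (nucleic acids) or any non-water heteroatom
#' component (ligands). Missing metadata flags the entry
#' "undetermined" and keeps it with a warning.
#'
#' @param entry One-row data.frame (needs pdb_id).
#' @param metadata List with `polymers` (character vector of polymer
#'   types, e.g. "protein", "dna", "rna") and `het` (character vector
#'   of heteroatom component codes, water = "HOH"), or NULL.
#' @param logger Optional function(character).
#' @return List with `keep` (logical), `reason` (character).
#' @export
filterProteinOnly <- function(entry, metadata, logger = NULL) {
  if (is.null(metadata)) {
    if (!is.null(logger))
      logger(sprintf("protein-only filter: %s metadata missing, kept as undetermined",
                     entry$pdb_id))
    return(list(keep = TRUE, reason = "undetermined"))
  }
  pol <- tolower(metadata$polymers %||% character(0))
  het <- toupper(metadata$het %||% character(0))
  nonProt <- setdiff(pol, "protein")
  lig <- setdiff(het, c("HOH", "WAT", "DOD"))
  if (length(nonProt))
    return(list(keep = FALSE, reason = "nucleic polymer"))
  if (length(lig))
    return(list(keep = FALSE, reason = "ligand"))
  list(keep = TRUE, reason = "protein only")
}

## ---- structure-quality scorers --------------------------------------

.scorerRegistry <- new.env(parent = emptyenv())

#' Register or look up structure-quality scorers
#'
#' A scorer is `function(structure)` returning a kJ/mol-scaled quality
#' score (lower is better). The built-in `"default-nb"` scorer is a
#' simple nonbonded pseudo-energy: a Lennard-Jones clash term over
#' non-bonded atom pairs plus a Coulomb term over the built-in
#' unit-scaled partial charges.
#'
#' @param name Scorer name.
#' @param fn Scorer function (for registration).
#' @return `registerScorer` the name invisibly; `getScorer` the
#'   function.
#' @export
registerScorer <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .scorerRegistry[[name]] <- fn
  invisible(name)
}

#' @rdname registerScorer
#' @export
getScorer <- function(name) {
  fn <- .scorerRegistry[[name]]
  if (is.null(fn))
    stop("unknown structure-quality scorer '", name, "'; registered: ",
         paste(ls(.scorerRegistry), collapse = ", "))
  fn
}

## LJ clash + Coulomb pseudo-energy, kJ/mol scale. Only pairs more
## than three covalent bonds apart count as nonbonded (1-2, 1-3 and
## 1-4 excluded entirely -- a coarse stand-in for the bonded terms
## and 1-4 scaling of a full force field); well-formed geometry then
## scores far below the default 1000 kJ/mol cutoff while overlapping
## atoms blow up through the r^-12 clash term.
.defaultNBScorer <- function(structure) {
  a <- atoms(structure)
  n <- nrow(a)
  if (n < 2L) return(0)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  q <- .PARTIAL_CHARGES[a$atom_name]
  q[is.na(q)] <- 0
  r0 <- .VDW_RADII[a$element]
  r0[is.na(r0)] <- 1.7
  nb <- .bondNeighbors(.bondList(structure), n)
  excl <- lapply(seq_len(n), function(i) .withinBonds(nb, i, 3L))
  e <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    j <- setdiff(j, excl[[i]])
    if (!length(j)) next
    dd <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    sig <- (r0[i] + r0[j]) * 0.8909     # LJ minimum at vdW contact
    x6 <- (sig / dd)^6
    e <- e + sum(0.4 * (x6 * x6 - x6))  # eps = 0.4 kJ/mol
    e <- e + sum(138.935 * q[i] * q[j] / dd)
  }
  e
}

#' Structure-quality (energy) filter
#'
#' Keeps a structure iff its quality score is at or below the cutoff
#' (the cutoff itself passes). A scorer failure drops the entry with
#' reason "unscorable".
#'
#' @param structure A [ProteinStructure-class].
#' @param cutoff Score cutoff on the kJ/mol scale; default 1000.
#' @param scorer Registered scorer name; default `"default-nb"`.
#' @param logger Optional function(character).
#' @return List with `keep`, `score`, `reason`.
#' @export
filterEnergy <- function(structure, cutoff = 1000, scorer = "default-nb",
                         logger = NULL) {
  fn <- getScorer(scorer)
  score <- tryCatch(fn(structure), error = function(e) NA_real_)
  if (is.na(score)) {
    if (!is.null(logger))
      logger(sprintf("energy filter: %s unscorable, dropped",
                     structure@pdbId))
    return(list(keep = FALSE, score = NA_real_, reason = "unscorable"))
  }
  keep <- score <= cutoff
  if (!is.null(logger) && !keep)
    logger(sprintf("energy filter: %s score %.1f > cutoff %.1f, dropped",
                   structure@pdbId, score, cutoff))
  list(keep = keep, score = score,
       reason = if (keep) "passed" else "energy above cutoff")
}
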