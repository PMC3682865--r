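## Linking experimental shifts to structure atoms: chain matching by
## best global alignment (ties to the first chain in file order),
## residue re-anchoring through the alignment's column map, atom-name
## conversion, and the per-record unmatched report.

## one-letter sequence of a shift entity: positions 1..max(seq index),
## 'X' where no shift row reports a residue
.entitySequence <- function(shiftRows) {
  idx <- shiftRows$residue_index
  if (!length(idx)) return("")
  seqv <- rep("X", max(idx))
  seqv[idx] <- threeToOne(shiftRows$residue_type)
  paste(seqv, collapse = "")
}

#' Match shift entities to structure chains
#'
#' Each shift entity is paired to the structure chain with the best
#' global-alignment identity between the entity's residue sequence
#' and the chain sequence; ties are broken by the first chain in file
#' order. Chains are already re-indexed 1..k in file order by
#' [parsePDB()].
#'
#' @param structure A [ProteinStructure-class].
#' @param shifts Shift table from [parseNMRStar()] (column `entity`
#'   groups chains on the shift side).
#' @param identityFloor Entities whose best identity falls below this
#'   are reported unmatched (default 0: never).
#' @param logger Optional function(character).
#' @return data.frame: entity, chain_index, identity; unmatched
#'   entities have NA chain_index.
#' @export
matchChains <- function(structure, shifts, identityFloor = 0,
                        logger = NULL) {
  chains <- chainSequences(structure)
  ents <- sort(unique(shifts$entity))
  out <- data.frame(entity = ents, chain_index = NA_integer_,
                    identity = NA_real_)
  for (k in seq_along(ents)) {
    erows <- shifts[shifts$entity == ents[k], , drop = FALSE]
    eseq <- .entitySequence(erows)
    best <- NA_integer_; bestId <- -1
    for (ci in as.integer(names(chains))) {
      id <- tryCatch(alignmentIdentity(eseq, chains[[as.character(ci)]]),
                     error = function(e) NA_real_)
      if (!is.na(id) && id > bestId + 1e-9) {  # strict: first chain wins ties
        bestId <- id; best <- ci
      }
    }
    if (!is.na(best) && bestId >= identityFloor) {
      out$chain_index[k] <- best
      out$identity[k] <- bestId
    } else if (!is.null(logger)) {
      logger(sprintf("chain matching: entity %s unmatched (best identity %.2f)",
                     ents[k], bestId))
    }
  }
  out
}

#' Assign experimental shifts to structure atoms
#'
#' Residue indices on the shift side are re-anchored onto the
#' structure through the global alignment of the two sequences, atom
#' names are converted to the structure's dialect, and each shift is
#' attached to exactly one atom or reported unmatched with a reason
#' (`no residue`, `no atom`, `name conversion failure`,
#' `unmatched entity`). Attached + unmatched always equals the parsed
#' shift count.
#'
#' @param structure A [ProteinStructure-class].
#' @param shifts Shift table from [parseNMRStar()].
#' @param pairing Chain pairing from [matchChains()]; computed when
#'   NULL.
#' @param scheme Super-class scheme used to label records.
#' @return List: `records` (data.frame of atom shift records) and
#'   `unmatched` (data.frame: entity, residue_index, atom_name,
#'   reason).
#' @export
assignShifts <- function(structure, shifts, pairing = NULL,
                         scheme = defaultSuperClassScheme()) {
  if (is.null(pairing)) pairing <- matchChains(structure, shifts)
  a <- atoms(structure)
  chains <- chainSequences(structure)
  recs <- list(); unm <- list()
  noteUnmatched <- function(row, reason)
    unm[[length(unm) + 1L]] <<- data.frame(
      entity = row$entity, residue_index = row$residue_index,
      atom_name = row$atom_name, reason = reason,
      stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairing))) {
    ent <- pairing$entity[k]
    ci <- pairing$chain_index[k]
    erows <- shifts[shifts$entity == ent, , drop = FALSE]
    if (is.na(ci)) {
      for (r in seq_len(nrow(erows)))
        noteUnmatched(erows[r, ], "unmatched entity")
      next
    }
    eseq <- .entitySequence(erows)
    al <- globalAlign(eseq, chains[[as.character(ci)]])
    idxMap <- .alignmentIndexMap(al$alignedA, al$alignedB)
    for (r in seq_len(nrow(erows))) {
      row <- erows[r, ]
      target <- if (row$residue_index >= 1 &&
                    row$residue_index <= length(idxMap))
        idxMap[row$residue_index] else NA_integer_
      if (is.na(target)) { noteUnmatched(row, "no residue"); next }
      rsel <- a$chain_index == ci & a$residue_index == target
      if (!any(rsel)) { noteUnmatched(row, "no residue"); next }
      resType <- a$residue_type[which(rsel)[1]]
      nm <- tryCatch(convertAtomName(resType, row$atom_name, to = "pdbv3"),
                     error = function(e) NULL)
      if (is.null(nm)) { noteUnmatched(row, "name conversion failure"); next }
      hit <- which(rsel & a$atom_name == nm)
      if (!length(hit)) { noteUnmatched(row, "no atom"); next }
      i <- hit[1]
      recs[[length(recs) + 1L]] <- data.frame(
        pdb_id = structure@pdbId, chain_index = ci,
        residue_index = target, residue_seq = a$residue_seq[i],
        residue_type = resType, atom_name = nm,
        ff_atom_type = tryCatch(.ffAtomType(resType, nm),
                                error = function(e) "DU"),
        super_class = assignSuperClass(nm, resType, scheme),
        experimental_shift = row$shift,
        ambiguity = row$ambiguity %||% NA_integer_,
        atom_row = i, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(pdb_id = character(0), chain_index = integer(0),
               residue_index = integer(0), residue_seq = integer(0),
               residue_type = character(0), atom_name = character(0),
               ff_atom_type = character(0), super_class = character(0),
               experimental_shift = numeric(0), ambiguity = integer(0),
               atom_row = integer(0), stringsAsFactors = FALSE)
  unmatched <- if (length(unm)) do.call(rbind, unm) else
    data.frame(entity = integer(0), residue_index = integer(0),
               atom_name = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  stopifnot(nrow(records) + nrow(unmatched) == nrow(shifts))
  list(records = records, unmatched = unmatched)
}

#' Write an unmatched-shift report as CSV
#'
#' @param unmatched data.frame from [assignShifts()].
#' @param pdbId Structure identifier added as a column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeUnmatchedReport <- function(unmatched, pdbId, path) {
  df <- cbind(pdb_id = rep(pdbId, nrow(unmatched)), unmatched)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
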