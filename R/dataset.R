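## Dataset assembly: from parsed structure + shift files through the
## filters and the feature engine to a ShiftDataset (and optionally
## the on-disk two-table store).

.emptyRecords <- function(features) {
  out <- data.frame(
    pdb_id = character(0), chain_index = integer(0),
    residue_index = integer(0), residue_seq = integer(0),
    residue_type = character(0), atom_name = character(0),
    ff_atom_type = character(0), super_class = character(0),
    experimental_shift = numeric(0), ambiguity = integer(0),
    stringsAsFactors = FALSE)
  kinds <- featureKindsOf(features)
  for (f in features)
    if (!f %in% names(out))
      out[[f]] <- if (kinds[[f]] == "categorical") character(0) else
        numeric(0)
  out
}

#' Construct a ShiftDataset from record and feature tables
#'
#' @param recs Atom shift records (from [assignShifts()]) joined with
#'   feature columns.
#' @param features Active feature names.
#' @param provenance Optional provenance list.
#' @return A [ShiftDataset-class], unpartitioned.
#' @export
makeShiftDataset <- function(recs, features = defaultFeatureDefinition(),
                             provenance = list()) {
  kinds <- featureKindsOf(features)
  new("ShiftDataset", records = recs, featureNames = features,
      featureKinds = kinds, partition = rep("unassigned", nrow(recs)),
      provenance = provenance)
}

#' Build a feature-annotated dataset from paired files
#'
#' The full preparation pipeline for a set of structure / shift-file
#' pairs: parse both files fault-tolerantly, match chains, apply the
#' mapping filters (perfect alignment; homology culling across
#' surviving chains; structure-quality score against the energy
#' cutoff), compute the feature table and attach each experimental
#' shift to its atom. Filter decisions are recorded per chain in the
#' mapping table (boolean filter-flag columns) and sent to `logger`.
#'
#' @param pairs data.frame with columns pdb_id, bmrb_id, pdb_path,
#'   star_path.
#' @param features Feature names to compute.
#' @param scheme Super-class scheme.
#' @param homologyCutoff Pairwise identity cutoff for culling
#'   (percent); NA skips culling. Default 10.
#' @param energyCutoff Structure-quality cutoff (kJ/mol scale); NA
#'   skips. Default 1000.
#' @param scorer Registered scorer name for the energy filter.
#' @param requirePerfectAlignment Keep only identity-100 chains
#'   (default TRUE).
#' @param shiftTransform Optional re-referencing hook: a function
#'   applied to the vector of parsed shift values (ppm) of each file
#'   before assignment. Default NULL = identity (no re-referencing).
#' @param storePath Optional path: write the two-table store.
#' @param logger Optional function(character) for the run log.
#' @return List: `dataset` ([ShiftDataset-class]), `mapping`
#'   (chain-mapping data.frame), `unmatched`, `reports` (per-file
#'   parse reports).
#' @export
buildDataset <- function(pairs, features = defaultFeatureDefinition(),
                         scheme = defaultSuperClassScheme(),
                         homologyCutoff = 10, energyCutoff = 1000,
                         scorer = "default-nb",
                         requirePerfectAlignment = TRUE,
                         shiftTransform = NULL,
                         storePath = NULL, logger = NULL) {
  say <- function(...) if (!is.null(logger)) logger(sprintf(...))
  mapRows <- list(); recRows <- list(); unmRows <- list(); reports <- list()
  chainSeqs <- character(0)

  for (k in seq_len(nrow(pairs))) {
    pid <- pairs$pdb_id[k]
    structure <- parsePDB(pairs$pdb_path[k])
    structure@pdbId <- pid
    parsed <- parseNMRStar(pairs$star_path[k])
    reports[[pid]] <- parsed$report
    if (!is.null(shiftTransform))
      parsed$shifts$shift <- shiftTransform(parsed$shifts$shift)
    if (sum(parsed$report$anomalies) > 0)
      say("parser: %s recovered %d anomaly(ies)", pid,
          sum(parsed$report$anomalies))
    pairing <- matchChains(structure, parsed$shifts, logger = logger)

    score <- NA_real_
    passedEnergy <- TRUE
    if (!is.na(energyCutoff)) {
      ef <- filterEnergy(structure, cutoff = energyCutoff,
                         scorer = scorer, logger = logger)
      score <- ef$score
      passedEnergy <- ef$keep
    }

    cond <- parsed$conditions
    el <- substr(sub("^[0-9]+", "", parsed$shifts$atom_name), 1, 1)
    hasH <- any(el == "H"); hasC <- any(el == "C"); hasN <- any(el == "N")

    asg <- assignShifts(structure, parsed$shifts, pairing, scheme)
    if (nrow(asg$unmatched)) {
      say("assignment: %s has %d unmatched shift(s)", pid,
          nrow(asg$unmatched))
      unmRows[[pid]] <- cbind(pdb_id = pid, asg$unmatched)
    }

    ft <- computeFeatureTable(structure, features, context = list(
      alignment_score = NA_real_,  # refined per chain below
      temperature = cond$temperature, ph = cond$ph,
      pressure = cond$pressure, solvent = cond$solvent,
      spectrometer = cond$spectrometer,
      has_h_shifts = as.numeric(hasH), has_c_shifts = as.numeric(hasC),
      has_n_shifts = as.numeric(hasN), structure_energy = score))

    aTab <- atoms(structure)
    for (j in seq_len(nrow(pairing))) {
      ci <- pairing$chain_index[j]
      if (is.na(ci)) next
      ident <- pairing$identity[j]
      passedAlign <- !requirePerfectAlignment || (!is.na(ident) &&
                                                  ident == 100)
      if (!passedAlign)
        say("alignment filter: %s chain %d identity %.2f != 100, dropped",
            pid, ci, ident)
      origChain <- aTab$chain_id[match(ci, aTab$chain_index)]
      mapRows[[length(mapRows) + 1L]] <- data.frame(
        pdb_id = pid, chain_index = ci, original_chain_id = origChain,
        bmrb_id = pairs$bmrb_id[k], alignment_identity = ident,
        has_h_shifts = hasH, has_c_shifts = hasC, has_n_shifts = hasN,
        temperature = cond$temperature, ph = cond$ph,
        pressure = cond$pressure,
        solvent = cond$solvent, spectrometer = cond$spectrometer,
        energy_score = score,
        passed_alignment = passedAlign, passed_energy = passedEnergy,
        stringsAsFactors = FALSE)
      if (passedAlign && passedEnergy) {
        key <- paste(pid, ci)
        chainSeqs[key] <- chainSequences(structure)[[as.character(ci)]]
        sel <- asg$records$chain_index == ci
        if (any(sel)) {
          rr <- asg$records[sel, , drop = FALSE]
          fr <- ft[rr$atom_row, , drop = FALSE]
          if ("alignment_score" %in% names(fr))
            fr$alignment_score <- ident
          rr <- rr[setdiff(names(rr), "atom_row")]
          ## identity columns double as features of the same name
          recRows[[key]] <- cbind(rr, fr[setdiff(names(fr), names(rr))])
        }
      }
    }
  }

  mapping <- if (length(mapRows)) do.call(rbind, mapRows) else
    data.frame(pdb_id = character(0), chain_index = integer(0))
  mapping$passed_homology <- NA

  keptKeys <- names(recRows)
  if (!is.na(homologyCutoff) && length(chainSeqs) > 1) {
    retained <- cullHomologs(chainSeqs, cutoff = homologyCutoff,
                             logger = logger)
    dropped <- setdiff(names(chainSeqs), retained)
    if (length(dropped))
      say("homology culling: dropped %d of %d chains", length(dropped),
          length(chainSeqs))
    keptKeys <- intersect(keptKeys, retained)
    mkey <- paste(mapping$pdb_id, mapping$chain_index)
    mapping$passed_homology <- ifelse(
      mkey %in% names(chainSeqs), mkey %in% retained, NA)
  }

  recs <- if (length(keptKeys))
    do.call(rbind, recRows[keptKeys]) else
    .emptyRecords(features)
  rownames(recs) <- NULL
  unmatched <- if (length(unmRows)) do.call(rbind, unmRows) else
    data.frame(pdb_id = character(0), entity = integer(0),
               residue_index = integer(0), atom_name = character(0),
               reason = character(0))
  rownames(unmatched) <- NULL

  ds <- makeShiftDataset(recs, features,
                         provenance = list(
                           n_pairs = nrow(pairs),
                           homologyCutoff = homologyCutoff,
                           energyCutoff = energyCutoff,
                           requirePerfectAlignment = requirePerfectAlignment))
  if (!is.null(storePath)) {
    dropCols <- intersect("ambiguity", names(recs))
    storeWrite(mapping, recs[setdiff(names(recs), dropCols)], storePath)
  }
  list(dataset = ds, mapping = mapping, unmatched = unmatched,
       reports = reports)
}

#' Load a ShiftDataset from a two-table store
#'
#' @param path Store file path.
#' @param features Feature names expected as columns; defaults to the
#'   intersection of the default definition with the stored columns.
#' @return A [ShiftDataset-class].
#' @export
datasetFromStore <- function(path, features = NULL) {
  st <- storeRead(path)
  if (is.null(features))
    features <- intersect(defaultFeatureDefinition(), names(st$atoms))
  makeShiftDataset(st$atoms, features,
                   provenance = list(source = path))
}
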