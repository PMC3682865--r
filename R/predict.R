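## Applying a trained model vector to a new structure: run the same
## preparation steps as dataset building (parse, featurize, super-class
## assignment), predict per class, and emit per-atom shifts as CSV.

#' Predict chemical shifts for a structure
#'
#' One prediction per atom whose name maps to a modeled super class;
#' atoms without a class are skipped and counted. The feature
#' definition must match the model's stored feature names exactly.
#' Experimental-condition features default to missing unless supplied
#' in `conditions`; the alignment-score feature is fixed to 100 (a
#' query structure has no reference sequence).
#'
#' @param x Path to a PDB file, or a [ProteinStructure-class].
#' @param mv A [ModelVector-class] (or a directory for
#'   [loadModels()]).
#' @param features Feature definition; default the model's stored
#'   names. A mismatch is an error listing the difference.
#' @param conditions Optional named list (temperature, ph, pressure,
#'   solvent, spectrometer).
#' @param scheme Super-class scheme; default the 10-class scheme.
#' @param out Optional CSV output path.
#' @return data.frame with columns pdb_id, chain, residue_index,
#'   residue_type, atom_name, super_class, predicted_shift_ppm; the
#'   number of skipped atoms in attribute `"skipped"`.
#' @export
predictStructure <- function(x, mv, features = NULL,
                             conditions = list(),
                             scheme = defaultSuperClassScheme(),
                             out = NULL) {
  structure <- if (is(x, "ProteinStructure")) x else parsePDB(x)
  if (is.character(mv)) mv <- loadModels(mv)
  if (is.null(features)) features <- featureNames(mv)
  if (!identical(sort(features), sort(featureNames(mv)))) {
    extra <- setdiff(features, featureNames(mv))
    miss <- setdiff(featureNames(mv), features)
    stop("feature definition does not match the model sidecar",
         if (length(extra)) paste0("; not in model: ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing: ",
                                  paste(miss, collapse = ", ")))
  }
  ctx <- list(alignment_score = 100,
              temperature = conditions$temperature %||% NA_real_,
              ph = conditions$ph %||% NA_real_,
              pressure = conditions$pressure %||% NA_real_,
              solvent = conditions$solvent %||% NA_character_,
              spectrometer = conditions$spectrometer %||% NA_character_,
              has_h_shifts = NA_real_, has_c_shifts = NA_real_,
              has_n_shifts = NA_real_, structure_energy = NA_real_)
  ft <- computeFeatureTable(structure, features, context = ctx)
  a <- atoms(structure)
  cls <- assignSuperClasses(a, scheme)
  covered <- !is.na(cls) & cls %in% classLabels(mv)
  skipped <- sum(!covered)
  rows <- which(covered)
  pred <- rep(NA_real_, length(rows))
  sub <- cbind(a[rows, , drop = FALSE], ft[rows, , drop = FALSE])
  for (lbl in unique(cls[rows])) {
    sel <- cls[rows] == lbl
    pred[sel] <- .predictClass(mv, lbl, sub[sel, , drop = FALSE])
  }
  res <- data.frame(
    pdb_id = structure@pdbId,
    chain = a$chain_index[rows],
    residue_index = a$residue_index[rows],
    residue_type = a$residue_type[rows],
    atom_name = a$atom_name[rows],
    super_class = cls[rows],
    predicted_shift_ppm = pred,
    stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  if (!is.null(out)) {
    df <- res
    df$predicted_shift_ppm <- sprintf("%.4f", df$predicted_shift_ppm)
    utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
  }
  res
}
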