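## S4 classes for the pipeline's central objects, with validity methods,
## show methods and accessors.

#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' ProteinStructure: atoms, residues and chains of one structure
#'
#' Holds the first NMR model of a PDB entry as a flat atom table.
#' Residue indices are 1-based in sequence order per (re-indexed) chain;
#' the depositor's own residue numbering is kept in `residue_seq`.
#'
#' @slot pdbId 4-character identifier (or fixture id).
#' @slot atoms data.frame with columns chain_id, chain_index,
#'   residue_index, residue_seq, residue_type, atom_name, element,
#'   x, y, z. Atom names in PDB-v3 spelling.
#' @slot metadata list (e.g. number of models in the source file).
#' @export
setClass("ProteinStructure",
         representation(pdbId = "character", atoms = "data.frame",
                        metadata = "list"),
         prototype(pdbId = "XXXX", metadata = list()))

setValidity("ProteinStructure", function(object) {
  need <- c("chain_id", "chain_index", "residue_index", "residue_seq",
            "residue_type", "atom_name", "element", "x", "y", "z")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste("atom table missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@atoms) &&
      !all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
           is.finite(object@atoms$z)))
    return("non-finite coordinates")
  TRUE
})

#' SuperClassScheme: partition of atom names into model classes
#'
#' @slot labels Ordered class labels.
#' @slot members Named list: per-class atom-name vocabularies
#'   (PDB-v2 dialect as used by the default scheme).
#' @slot provenance "default", "user" or "auto".
#' @export
setClass("SuperClassScheme",
         representation(labels = "character", members = "list",
                        provenance = "character"),
         prototype(provenance = "user"))

setValidity("SuperClassScheme", function(object) {
  if (!identical(sort(object@labels), sort(names(object@members))))
    return("labels and member-list names differ")
  all_names <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_names))
    return(paste("atom names in multiple classes:",
                 paste(unique(all_names[duplicated(all_names)]),
                       collapse = ", ")))
  TRUE
})

#' ShiftDataset: feature-annotated atom shift records with partition
#'
#' @slot records data.frame: one row per atom with identity columns
#'   (pdb_id, chain_index, residue_index, residue_type, atom_name,
#'   ff_atom_type, super_class, experimental_shift) plus one column per
#'   feature.
#' @slot featureNames Active feature names (column subset).
#' @slot featureKinds Named character: "numeric" or "categorical".
#' @slot partition Character vector along rows: "train", "test" or
#'   "unassigned".
#' @slot provenance list: source, filters applied, seed.
#' @export
setClass("ShiftDataset",
         representation(records = "data.frame", featureNames = "character",
                        featureKinds = "character", partition = "character",
                        provenance = "list"),
         prototype(provenance = list()))

setValidity("ShiftDataset", function(object) {
  if (length(object@partition) != nrow(object@records))
    return("partition length != record count")
  if (!all(object@partition %in% c("train", "test", "unassigned")))
    return("invalid partition label")
  miss <- setdiff(object@featureNames, names(object@records))
  if (length(miss))
    return(paste("feature columns missing:", paste(miss, collapse = ", ")))
  if (nrow(object@records) &&
      !all(is.finite(object@records$experimental_shift)))
    return("non-finite experimental shift")
  key <- do.call(paste, c(object@records[c("pdb_id", "chain_index",
                                           "residue_index", "atom_name")],
                          sep = "\r"))
  if (anyDuplicated(key))
    return("duplicate (pdb_id, chain_index, residue_index, atom_name) key")
  TRUE
})

#' ModelVector: one fitted regressor per atom super class
#'
#' @slot models Named list of fitted backend models.
#' @slot featureNames Feature names the models consume, in order.
#' @slot featureKinds Named character, "numeric"/"categorical".
#' @slot encodings Per-categorical-feature level sets (one-hot encoding).
#' @slot imputation Per-class named numeric medians for missing values.
#' @slot metadata list: backend, ntree, per-class mtry and n, seed,
#'   format version.
#' @export
setClass("ModelVector",
         representation(models = "list", featureNames = "character",
                        featureKinds = "character", encodings = "list",
                        imputation = "list", metadata = "list"))

#' EvaluationResult: per-super-class rmse and correlation
#'
#' @slot table data.frame: super_class, n, rmse, corr, mean_exp,
#'   mean_pred, sd_exp, sd_pred (sample standard deviations).
#' @slot pooled list: n, rmse, corr over all test records.
#' @export
setClass("EvaluationResult",
         representation(table = "data.frame", pooled = "list"))

setValidity("EvaluationResult", function(object) {
  tb <- object@table
  if (nrow(tb)) {
    ok <- is.na(tb$corr) | (tb$corr >= -1 - 1e-12 & tb$corr <= 1 + 1e-12)
    if (!all(ok)) return("corr outside [-1, 1]")
    if (!all(is.na(tb$rmse) | tb$rmse >= 0)) return("negative rmse")
  }
  TRUE
})

## ---- accessors & show ------------------------------------------------

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("chainSequences", function(x) standardGeneric("chainSequences"))
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @export
setGeneric("classMembers", function(x, label) standardGeneric("classMembers"))
#' @export
setGeneric("evalTable", function(x) standardGeneric("evalTable"))
#' @export
setGeneric("pooledMetrics", function(x) standardGeneric("pooledMetrics"))

#' @describeIn ProteinStructure-class atom table accessor
#' @param x object
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @describeIn ProteinStructure-class one-letter sequence per chain_index
#' @export
setMethod("chainSequences", "ProteinStructure", function(x) {
  a <- x@atoms
  out <- character(0)
  for (ci in sort(unique(a$chain_index))) {
    sub <- a[a$chain_index == ci, ]
    res <- sub[!duplicated(sub$residue_index), ]
    res <- res[order(res$residue_index), ]
    out[as.character(ci)] <- paste(threeToOne(res$residue_type),
                                   collapse = "")
  }
  out
})

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure", object@pdbId, "--",
      length(unique(a$chain_index)), "chain(s),",
      length(unique(paste(a$chain_index, a$residue_index))), "residues,",
      nrow(a), "atoms\n")
})

#' @describeIn SuperClassScheme-class ordered class labels
#' @param x object
#' @export
setMethod("classLabels", "SuperClassScheme", function(x) x@labels)

#' @describeIn SuperClassScheme-class atom-name vocabulary of one class
#' @param label class label
#' @export
setMethod("classMembers", "SuperClassScheme",
          function(x, label) x@members[[label]])

setMethod("show", "SuperClassScheme", function(object) {
  cat("SuperClassScheme (", object@provenance, "): ",
      length(object@labels), " classes\n", sep = "")
  for (l in object@labels)
    cat("  ", l, ": ", paste(object@members[[l]], collapse = ", "),
        "\n", sep = "")
})

#' @describeIn ShiftDataset-class record table accessor
#' @param x object
#' @export
setMethod("records", "ShiftDataset", function(x) x@records)

#' @describeIn ShiftDataset-class partition labels along rows
#' @export
setMethod("partitionLabels", "ShiftDataset", function(x) x@partition)

#' @describeIn ShiftDataset-class active feature names
#' @export
setMethod("featureNames", "ShiftDataset", function(x) x@featureNames)

setMethod("show", "ShiftDataset", function(object) {
  cat("ShiftDataset:", nrow(object@records), "atom shift records,",
      length(object@featureNames), "features\n")
  cat("  partition:", sum(object@partition == "train"), "train /",
      sum(object@partition == "test"), "test /",
      sum(object@partition == "unassigned"), "unassigned\n")
})

#' @describeIn ModelVector-class feature names consumed by the models
#' @param x object
#' @export
setMethod("featureNames", "ModelVector", function(x) x@featureNames)

#' @describeIn ModelVector-class labels of the fitted classes
#' @export
setMethod("classLabels", "ModelVector", function(x) names(x@models))

setMethod("show", "ModelVector", function(object) {
  cat("ModelVector:", length(object@models), "per-class",
      object@metadata$backend %||% "rf", "models;",
      length(object@featureNames), "features\n")
  n <- object@metadata$nTrain
  if (!is.null(n))
    cat("  classes:", paste(sprintf("%s(n=%d)", names(object@models),
                                    unlist(n)[names(object@models)]),
                            collapse = ", "), "\n")
})

#' @describeIn EvaluationResult-class per-class metric table
#' @param x object
#' @export
setMethod("evalTable", "EvaluationResult", function(x) x@table)

#' @describeIn EvaluationResult-class pooled n/rmse/corr list
#' @export
setMethod("pooledMetrics", "EvaluationResult", function(x) x@pooled)

setMethod("show", "EvaluationResult", function(object) {
  cat("EvaluationResult (per atom super class):\n")
  tb <- object@table
  tb$rmse <- round(tb$rmse, 4)
  tb$corr <- round(tb$corr, 4)
  print(tb[c("super_class", "n", "rmse", "corr")], row.names = FALSE)
  p <- object@pooled
  cat(sprintf("pooled: n=%d rmse=%.4f corr=%.4f\n", p$n, p$rmse, p$corr))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
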