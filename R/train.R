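## Training and evaluation: dataset splitting by structure, one
## random-forest model per atom super class (500 trees, mtry tuned by
## an out-of-bag doubling/halving sweep), and the two evaluation
## metrics -- root-mean-square error and the sample-normalized Pearson
## correlation -- implemented literally from their defining formulas.

#' Root-mean-square error between experimental and predicted shifts
#'
#' `rmse = sqrt( sum_i (exp_i - pred_i)^2 / n )`.
#'
#' @param expShift,predShift Numeric vectors (ppm).
#' @return RMSE in ppm.
#' @export
shiftRmse <- function(expShift, predShift) {
  stopifnot(length(expShift) == length(predShift))
  n <- length(expShift)
  if (n == 0L) return(NA_real_)
  sqrt(sum((expShift - predShift)^2) / n)
}

#' Pearson correlation between experimental and predicted shifts
#'
#' `corr = 1/(n-1) * sum_i ((exp_i - mean_exp)/s_exp) *
#' ((pred_i - mean_pred)/s_pred)` with sample (n-1) standard
#' deviations. Undefined (NA) for n < 2 or zero-variance input.
#'
#' @param expShift,predShift Numeric vectors (ppm).
#' @return Correlation in \[-1, 1\], or NA.
#' @export
shiftCorr <- function(expShift, predShift) {
  stopifnot(length(expShift) == length(predShift))
  n <- length(expShift)
  if (n < 2L) return(NA_real_)
  se <- stats::sd(expShift); sp <- stats::sd(predShift)
  if (se == 0 || sp == 0) return(NA_real_)
  me <- mean(expShift); mp <- mean(predShift)
  sum(((expShift - me) / se) * ((predShift - mp) / sp)) / (n - 1)
}

#' Split a dataset into training and test partitions by structure
#'
#' The split granularity is the structure: all records of one pdb_id
#' land on the same side, preventing leakage of intra-protein
#' correlation. The number of training structures is
#' `floor(n * trainFraction + 0.5)` (round half up). Deterministic
#' per seed.
#'
#' @param dataset A [ShiftDataset-class] with unassigned records.
#' @param trainFraction Fraction of structures for training; default
#'   0.6 (a 60:40 split).
#' @param seed Integer RNG seed.
#' @return The dataset with partition labels set.
#' @export
splitDataset <- function(dataset, trainFraction = 0.6, seed = 1L) {
  recs <- records(dataset)
  if (nrow(recs) == 0L) stop("cannot split an empty dataset")
  stopifnot(trainFraction > 0, trainFraction < 1)
  if (any(partitionLabels(dataset) != "unassigned"))
    stop("dataset is already partitioned")
  ids <- unique(recs$pdb_id)
  nTrain <- floor(length(ids) * trainFraction + 0.5)
  set.seed(as.integer(seed))
  trainIds <- sample(ids, nTrain)
  part <- ifelse(recs$pdb_id %in% trainIds, "train", "test")
  prov <- dataset@provenance
  prov$split <- list(trainFraction = trainFraction, seed = seed,
                     nTrain = nTrain, nTest = length(ids) - nTrain)
  methods::initialize(dataset, partition = part, provenance = prov)
}

## ---- design matrix ---------------------------------------------------

## One-hot encoding with stored levels; numeric NAs imputed by stored
## medians with a parallel <name>_missing indicator column.
.designMatrix <- function(recs, featureNames, featureKinds,
                          encodings = NULL, medians = NULL) {
  fit <- is.null(encodings)
  if (fit) { encodings <- list(); medians <- c() }
  cols <- list()
  for (f in featureNames) {
    v <- recs[[f]]
    if (featureKinds[[f]] == "categorical") {
      v <- as.character(v)
      v[is.na(v)] <- "missing"
      if (fit) encodings[[f]] <- sort(unique(v))
      for (lev in encodings[[f]])
        cols[[paste0(f, ".", lev)]] <- as.numeric(v == lev)
    } else {
      v <- as.numeric(v)
      missing <- as.numeric(!is.finite(v))
      if (fit) {
        med <- stats::median(v[is.finite(v)])
        if (!is.finite(med)) med <- 0
        medians[[f]] <- med
      }
      v[!is.finite(v)] <- medians[[f]]
      cols[[f]] <- v
      cols[[paste0(f, "_missing")]] <- missing
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, encodings = encodings, medians = medians)
}

## ---- hybrid baseline -------------------------------------------------

## The models are hybrid: a fixed semi-classical baseline (the sum of
## the random-coil and ring-current feature columns, with missing
## entries contributing 0) plus a statistical model of the residual.
## The steep, physically known terms are thereby predicted exactly
## instead of being approximated by the forest.
.BASELINE_FEATURES <- c("random_coil", "ring_current")

.hybridBaseline <- function(rows, featureNames) {
  b <- rep(0, nrow(rows))
  for (f in intersect(.BASELINE_FEATURES, featureNames)) {
    v <- as.numeric(rows[[f]])
    v[!is.finite(v)] <- 0
    b <- b + v
  }
  b
}

## ---- model backends --------------------------------------------------

.modelBackends <- new.env(parent = emptyenv())

#' Register or look up a regression backend
#'
#' A backend is a list of functions `train(X, y, control)`,
#' `predict(model, X)` and optionally `importance(model)`. The
#' built-in `"rf"` backend wraps randomForest with 500 trees and an
#' out-of-bag doubling/halving mtry sweep.
#'
#' @param name Backend name.
#' @param backend Backend list (for registration).
#' @return `registerModelBackend` the name invisibly;
#'   `getModelBackend` the backend.
#' @export
registerModelBackend <- function(name, backend) {
  stopifnot(is.list(backend), is.function(backend$train),
            is.function(backend$predict))
  .modelBackends[[name]] <- backend
  invisible(name)
}

#' @rdname registerModelBackend
#' @export
getModelBackend <- function(name) {
  b <- .modelBackends[[name]]
  if (is.null(b))
    stop("unknown model backend '", name, "'; registered: ",
         paste(ls(.modelBackends), collapse = ", "))
  b
}

.tuneMtry <- function(X, y, ntree) {
  p <- ncol(X)
  start <- max(1L, floor(p / 3))
  res <- tryCatch({
    out <- NULL
    utils::capture.output(out <- suppressWarnings(randomForest::tuneRF(
      X, y, mtryStart = start, ntreeTry = min(ntree, 100L),
      stepFactor = 2, improve = 0.01, trace = FALSE, plot = FALSE)))
    out
  }, error = function(e) NULL)
  if (is.null(res)) return(start)
  as.integer(res[which.min(res[, 2]), 1])
}

.rfBackend <- function() {
  list(
    train = function(X, y, control) {
      mtry <- if (isTRUE(control$tuneMtry))
        .tuneMtry(X, y, control$ntree) else
        max(1L, floor(ncol(X) / 3))
      model <- randomForest::randomForest(
        x = X, y = y, ntree = control$ntree, mtry = mtry)
      attr(model, "mtry_used") <- mtry
      model
    },
    predict = function(model, X) as.numeric(stats::predict(model, X)),
    importance = function(model) {
      imp <- randomForest::importance(model)
      v <- imp[, 1]
      names(v) <- rownames(imp)
      v
    })
}

#' Train one model per atom super class
#'
#' The fitted models are hybrid: the semi-classical baseline (random
#' coil + ring current, taken from the feature columns) is added as-is
#' and the statistical backend models the residual shift.
#' Records of the training partition are grouped by super class;
#' classes with fewer rows than `minClassSize` are skipped with a
#' warning. Categorical features are one-hot encoded (the encoding is
#' stored for prediction); missing numeric values are imputed by the
#' per-class training median alongside a missing-indicator column.
#'
#' @param dataset A partitioned [ShiftDataset-class].
#' @param scheme Super-class scheme (labels to train); default the
#'   10-class scheme.
#' @param backend Registered backend name; default `"rf"`.
#' @param ntree Trees per forest; default 500.
#' @param minClassSize Minimum training rows per class; default 50.
#' @param tuneMtry Tune mtry by the backend's out-of-bag sweep;
#'   default TRUE.
#' @param seed Integer RNG seed.
#' @return A [ModelVector-class].
#' @export
trainModels <- function(dataset, scheme = defaultSuperClassScheme(),
                        backend = "rf", ntree = 500L, minClassSize = 50L,
                        tuneMtry = TRUE, seed = 1L) {
  be <- getModelBackend(backend)
  recs <- records(dataset)
  train <- recs[partitionLabels(dataset) == "train", , drop = FALSE]
  if (!nrow(train)) stop("empty training partition")
  featureNames <- featureNames(dataset)
  featureKinds <- dataset@featureKinds[featureNames]
  models <- list(); encodings <- list(); imputation <- list()
  mtryUsed <- list(); nTrain <- list()
  set.seed(as.integer(seed))
  for (lbl in classLabels(scheme)) {
    rows <- train[!is.na(train$super_class) & train$super_class == lbl, ,
                  drop = FALSE]
    if (nrow(rows) < minClassSize) {
      warning("super class ", lbl, " has ", nrow(rows),
              " training rows (< ", minClassSize, "); skipped")
      next
    }
    dm <- .designMatrix(rows, featureNames, featureKinds)
    ctl <- list(ntree = as.integer(ntree), tuneMtry = tuneMtry)
    resid <- rows$experimental_shift - .hybridBaseline(rows, featureNames)
    model <- be$train(dm$X, resid, ctl)
    models[[lbl]] <- model
    encodings[[lbl]] <- dm$encodings
    imputation[[lbl]] <- dm$medians
    mtryUsed[[lbl]] <- attr(model, "mtry_used")
    nTrain[[lbl]] <- nrow(rows)
  }
  if (!length(models)) stop("no super class reached the minimum class size")
  new("ModelVector", models = models, featureNames = featureNames,
      featureKinds = featureKinds, encodings = encodings,
      imputation = imputation,
      metadata = list(backend = backend, ntree = as.integer(ntree),
                      seed = as.integer(seed), mtry = mtryUsed,
                      nTrain = nTrain, version = 1L))
}

.predictClass <- function(mv, lbl, rows) {
  be <- getModelBackend(mv@metadata$backend)
  dm <- .designMatrix(rows, mv@featureNames, mv@featureKinds,
                      encodings = mv@encodings[[lbl]],
                      medians = mv@imputation[[lbl]])
  .hybridBaseline(rows, mv@featureNames) +
    be$predict(mv@models[[lbl]], dm$X)
}

#' Evaluate a model vector on the test partition
#'
#' Computes per-class n, rmse and corr (with means and sample
#' standard deviations of experimental and predicted shifts) plus the
#' pooled metrics over all covered test records. Classes with n < 2
#' or zero-variance predictions report corr as NA.
#'
#' @param mv A [ModelVector-class].
#' @param dataset A partitioned [ShiftDataset-class].
#' @return An [EvaluationResult-class].
#' @export
evaluateModels <- function(mv, dataset) {
  recs <- records(dataset)
  test <- recs[partitionLabels(dataset) == "test", , drop = FALSE]
  rows <- list(); allExp <- c(); allPred <- c()
  for (lbl in names(mv@models)) {
    sub <- test[!is.na(test$super_class) & test$super_class == lbl, ,
                drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) {
      rows[[lbl]] <- data.frame(super_class = lbl, n = 0L, rmse = NA_real_,
                                corr = NA_real_, mean_exp = NA_real_,
                                mean_pred = NA_real_, sd_exp = NA_real_,
                                sd_pred = NA_real_)
      next
    }
    pred <- .predictClass(mv, lbl, sub)
    e <- sub$experimental_shift
    rows[[lbl]] <- data.frame(
      super_class = lbl, n = n, rmse = shiftRmse(e, pred),
      corr = shiftCorr(e, pred), mean_exp = mean(e),
      mean_pred = mean(pred),
      sd_exp = if (n > 1) stats::sd(e) else NA_real_,
      sd_pred = if (n > 1) stats::sd(pred) else NA_real_)
    allExp <- c(allExp, e); allPred <- c(allPred, pred)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pooled <- list(n = length(allExp),
                 rmse = shiftRmse(allExp, allPred),
                 corr = shiftCorr(allExp, allPred))
  new("EvaluationResult", table = tab, pooled = pooled)
}

#' Ranked feature importances per super class
#'
#' @param mv A [ModelVector-class].
#' @return Named list (per class) of data.frames feature/importance,
#'   descending; empty with a warning when the backend exposes none.
#' @export
featureImportanceTable <- function(mv) {
  be <- getModelBackend(mv@metadata$backend)
  if (is.null(be$importance)) {
    warning("backend '", mv@metadata$backend, "' exposes no importances")
    return(setNames(vector("list", 0), character(0)))
  }
  out <- list()
  for (lbl in names(mv@models)) {
    v <- be$importance(mv@models[[lbl]])
    v <- sort(v, decreasing = TRUE)
    out[[lbl]] <- data.frame(feature = names(v), importance = as.numeric(v),
                             stringsAsFactors = FALSE)
  }
  out
}

## ---- persistence -----------------------------------------------------

#' Save / load a model vector
#'
#' One binary artifact per class plus a JSON sidecar describing the
#' feature names, kinds, encodings, imputation medians and metadata,
#' so a stored model is portable and self-describing.
#'
#' @param mv A [ModelVector-class].
#' @param dir Directory (created if needed).
#' @return `saveModels` the directory invisibly; `loadModels` the
#'   [ModelVector-class].
#' @export
saveModels <- function(mv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lbl in names(mv@models))
    saveRDS(mv@models[[lbl]], file.path(dir, paste0("class_", lbl, ".rds")))
  sidecar <- list(
    format_version = mv@metadata$version %||% 1L,
    backend = mv@metadata$backend,
    featureNames = mv@featureNames,
    featureKinds = as.list(mv@featureKinds),
    encodings = mv@encodings,
    imputation = lapply(mv@imputation, as.list),
    metadata = mv@metadata[setdiff(names(mv@metadata), "mtry")],
    classes = names(mv@models))
  jsonlite::write_json(sidecar, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveModels
#' @export
loadModels <- function(dir) {
  sidePath <- file.path(dir, "models.json")
  if (!file.exists(sidePath)) stop("no models.json sidecar in ", dir)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  models <- list()
  for (lbl in side$classes)
    models[[lbl]] <- readRDS(file.path(dir, paste0("class_", lbl, ".rds")))
  enc <- lapply(side$encodings, function(e) lapply(e, as.character))
  imp <- lapply(side$imputation, function(m) unlist(m))
  meta <- side$metadata
  meta$backend <- side$backend
  new("ModelVector", models = models,
      featureNames = as.character(side$featureNames),
      featureKinds = unlist(side$featureKinds),
      encodings = enc, imputation = imp, metadata = as.list(meta))
}
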