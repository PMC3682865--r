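## a synthetic one-class dataset with a known linear generator
linearDataset <- function(n = 2000, noise = 0, seed = 5,
                          betas = c(featA = 2, featB = -1)) {
  set.seed(seed)
  featA <- rnorm(n); featB <- rnorm(n); featC <- rnorm(n)
  shift <- betas[["featA"]] * featA + betas[["featB"]] * featB +
    rnorm(n, 0, noise)
  recs <- data.frame(
    pdb_id = sprintf("P%03d", rep(seq_len(max(2, n %/% 100)),
                                  length.out = n)),
    chain_index = 1L, residue_index = seq_len(n), residue_seq = seq_len(n),
    residue_type = "ALA", atom_name = "CA", ff_atom_type = "CX",
    super_class = "CA", experimental_shift = shift,
    featA = featA, featB = featB, featC = featC,
    stringsAsFactors = FALSE)
  for (f in c("featA", "featB", "featC"))
    if (is.null(.featureCacheRegistered[[f]])) {
      registerFeature(f, "numeric", function(s, ctx)
        stop("synthetic feature; never computed"), overwrite = TRUE)
      .featureCacheRegistered[[f]] <- TRUE
    }
  makeShiftDataset(recs, features = c("featA", "featB", "featC"))
}
.featureCacheRegistered <- new.env(parent = emptyenv())

oneClassScheme <- new("SuperClassScheme", labels = "CA",
                      members = list(CA = "CA"), provenance = "user")

test_that("rmse and corr match direct textbook recomputation", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:20, 1)
    e <- rnorm(n, 10, 3); p <- rnorm(n, 10, 3)
    expect_equal(shiftRmse(e, p), sqrt(mean((e - p)^2)),
                 tolerance = 1e-12)
    expect_equal(shiftCorr(e, p), cor(e, p), tolerance = 1e-12)
  }
  expect_equal(shiftRmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(shiftCorr(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(shiftCorr(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(shiftRmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  ## undefined cases are NA, not 0
  expect_true(is.na(shiftCorr(1, 2)))
  expect_true(is.na(shiftCorr(c(1, 2), c(5, 5))))
})

test_that("splitting is by structure with round-half-up counts", {
  ds <- linearDataset(n = 1000)       # 10 structures of 100
  sp <- splitDataset(ds, 0.6, seed = 9)
  r <- records(sp); part <- partitionLabels(sp)
  trainIds <- unique(r$pdb_id[part == "train"])
  testIds <- unique(r$pdb_id[part == "test"])
  expect_equal(length(trainIds), 6)
  expect_equal(length(testIds), 4)
  expect_length(intersect(trainIds, testIds), 0)
  ## same seed reproduces the partition; a new seed changes membership
  sp2 <- splitDataset(ds, 0.6, seed = 9)
  expect_identical(partitionLabels(sp2), part)
  sp3 <- splitDataset(ds, 0.6, seed = 10)
  expect_equal(length(unique(records(sp3)$pdb_id[
    partitionLabels(sp3) == "train"])), 6)
  expect_false(identical(partitionLabels(sp3), part))
  ## 5 structures: round half up gives 3 train / 2 test
  ds5 <- linearDataset(n = 500)
  sp5 <- splitDataset(ds5, 0.6, seed = 1)
  expect_equal(length(unique(records(sp5)$pdb_id[
    partitionLabels(sp5) == "train"])), 3)
  expect_error(splitDataset(sp5), "already partitioned")
  expect_error(splitDataset(makeShiftDataset(
    records(ds5)[0, ], featureNames(ds5))), "empty")
})

test_that("training recovers a noiseless linear generator", {
  ds <- splitDataset(linearDataset(n = 2000), 0.6, seed = 2)
  mv <- trainModels(ds, scheme = oneClassScheme, seed = 2)
  r <- records(ds)
  tr <- r[partitionLabels(ds) == "train", ]
  pred <- ShiftForge:::.predictClass(mv, "CA", tr)
  expect_lt(shiftRmse(tr$experimental_shift, pred),
            0.1 * sd(tr$experimental_shift))
})

test_that("small classes are skipped and bad backends rejected", {
  ds <- splitDataset(linearDataset(n = 200), 0.6, seed = 3)
  expect_warning(
    expect_error(trainModels(ds, scheme = oneClassScheme,
                             minClassSize = 500),
                 "no super class"),
    "skipped")
  expect_error(trainModels(ds, scheme = oneClassScheme,
                           backend = "deep-net"), "unknown model backend")
})

test_that("evaluation reports the defining metrics per class", {
  ds <- splitDataset(linearDataset(n = 2000), 0.6, seed = 4)
  mv <- trainModels(ds, scheme = oneClassScheme, seed = 4)
  ev <- evaluateModels(mv, ds)
  tb <- evalTable(ev)
  expect_equal(tb$super_class, "CA")
  expect_equal(tb$n, sum(partitionLabels(ds) == "test"))
  expect_gt(tb$corr, 0.9)
  expect_lt(tb$rmse, 0.5 * tb$sd_exp)
  p <- pooledMetrics(ev)
  expect_equal(p$n, tb$n)
})

test_that("noisy linear data yields rmse near the noise floor", {
  sigma <- 1
  ds <- splitDataset(linearDataset(n = 5000, noise = sigma, seed = 6,
                                   betas = c(featA = 4, featB = -3)),
                     0.6, seed = 6)
  mv <- trainModels(ds, scheme = oneClassScheme, seed = 6)
  ev <- evaluateModels(mv, ds)
  tb <- evalTable(ev)
  expect_gte(tb$rmse, 0.9 * sigma)
  expect_lte(tb$rmse, 1.5 * sigma)
  expect_gte(tb$corr, 0.9)
})

test_that("feature importance ranks the generating feature first", {
  set.seed(7)
  ds <- splitDataset(linearDataset(n = 1500, betas = c(featA = 3,
                                                       featB = 0)),
                     0.6, seed = 7)
  mv <- trainModels(ds, scheme = oneClassScheme, seed = 7)
  imp <- featureImportanceTable(mv)$CA
  expect_equal(imp$feature[1], "featA")
  expect_true(all(diff(imp$importance) <= 0))
  ## the pure-noise feature ranks below the signal feature
  expect_lt(imp$importance[imp$feature == "featC"],
            imp$importance[imp$feature == "featA"])
})

test_that("models persist with a JSON sidecar and reload identically", {
  ds <- splitDataset(linearDataset(n = 600), 0.6, seed = 8)
  mv <- trainModels(ds, scheme = oneClassScheme, seed = 8)
  dir <- withr::local_tempdir()
  saveModels(mv, dir)
  expect_true(file.exists(file.path(dir, "models.json")))
  mv2 <- loadModels(dir)
  te <- records(ds)[partitionLabels(ds) == "test", ]
  expect_equal(ShiftForge:::.predictClass(mv2, "CA", te),
               ShiftForge:::.predictClass(mv, "CA", te),
               tolerance = 1e-12)
  expect_identical(featureNames(mv2), featureNames(mv))
})
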