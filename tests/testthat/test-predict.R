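## shared tiny trained model over fixture proteins
predictFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "predict-fixtures")
    fx <- buildFixtureSet(dir, nProteins = 5, lengthRange = c(14L, 16L),
                          sigma = 0, seed = 3)
    built <- buildDataset(fx$pairs, homologyCutoff = NA,
                          energyCutoff = NA)
    ds <- splitDataset(built$dataset, 0.6, seed = 3)
    mv <- trainModels(ds, ntree = 60, minClassSize = 10, seed = 3,
                      tuneMtry = FALSE)
    cache <<- list(fx = fx, ds = ds, mv = mv)
    cache
  }
})

test_that("prediction emits one row per modeled atom and skips the rest", {
  pf <- predictFixture()
  res <- predictStructure(pf$fx$pairs$pdb_path[1], pf$mv)
  expect_true(all(is.finite(res$predicted_shift_ppm)))
  expect_true(all(res$super_class %in% classLabels(pf$mv)))
  a <- atoms(parsePDB(pf$fx$pairs$pdb_path[1]))
  expect_equal(nrow(res) + attr(res, "skipped"), nrow(a))
  expect_gt(attr(res, "skipped"), 0)   # O and side-chain C atoms
})

test_that("prediction is deterministic down to the CSV bytes", {
  pf <- predictFixture()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  predictStructure(pf$fx$pairs$pdb_path[2], pf$mv, out = f1)
  predictStructure(pf$fx$pairs$pdb_path[2], pf$mv, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  hdr <- readLines(f1, n = 1)
  expect_identical(hdr, paste("pdb_id,chain,residue_index,residue_type",
                              "atom_name,super_class,predicted_shift_ppm",
                              sep = ","))
})

test_that("predictions agree with evaluation-time predictions", {
  pf <- predictFixture()
  te <- records(pf$ds)[partitionLabels(pf$ds) == "test", ]
  id <- te$pdb_id[1]
  path <- pf$fx$pairs$pdb_path[pf$fx$pairs$pdb_id == id]
  res <- predictStructure(path, pf$mv)
  sub <- te[te$super_class == "CA" & !is.na(te$super_class), ]
  sub <- sub[sub$pdb_id == id, ]
  evPred <- ShiftForge:::.predictClass(pf$mv, "CA", sub)
  got <- res$predicted_shift_ppm[res$super_class == "CA"]
  got <- got[match(sub$residue_index,
                   res$residue_index[res$super_class == "CA"])]
  ## same features except experimental context; CA features are all
  ## structural here, so values agree to numerical identity
  expect_equal(got, evPred, tolerance = 1e-9)
})

test_that("a feature-definition mismatch is a listed error", {
  pf <- predictFixture()
  expect_error(
    predictStructure(pf$fx$pairs$pdb_path[1], pf$mv,
                     features = c(featureNames(pf$mv)[-1], "ring_current2")),
    "does not match the model sidecar")
})
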