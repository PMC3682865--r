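## The end-to-end synthetic study (the package's default fixture
## cohort) is expensive, so it is built once per test run and shared.
## Noisy and permuted variants reuse the featurized records and
## replace only the shift column, exactly as the generator would
## (its noise is additive on the deterministic part).

.e2eCache <- new.env(parent = emptyenv())

e2eStudy <- function(seed = 1L) {
  key <- as.character(seed)
  if (!is.null(.e2eCache[[key]])) return(.e2eCache[[key]])
  dir <- file.path(tempdir(), paste0("e2e-fixtures-", seed))
  fx <- buildFixtureSet(dir, sigma = 0, seed = seed)
  built <- buildDataset(fx$pairs, homologyCutoff = NA)
  ds0 <- splitDataset(built$dataset, 0.6, seed = seed + 1L)
  mv0 <- trainModels(ds0, seed = seed + 2L)
  ev0 <- evaluateModels(mv0, ds0)
  out <- list(fx = fx, built = built, ds0 = ds0, mv0 = mv0, ev0 = ev0)
  .e2eCache[[key]] <- out
  out
}

## same partition and features, new shift column
e2eVariant <- function(study, shifts) {
  recs <- records(study$ds0)
  recs$experimental_shift <- shifts
  methods::initialize(study$ds0, records = recs)
}
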