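## a small hand-assembled shift table used by most parser tests
makeShiftTable <- function(n = 12) {
  res <- rep(c("ALA", "SER", "GLY"), length.out = n)
  atom <- rep(c("CA", "HA", "N", "H"), length.out = n)
  data.frame(entity = 1L, residue_index = rep(seq_len(ceiling(n / 4)),
                                              each = 4)[seq_len(n)],
             residue_type = res, atom_name = atom,
             shift = round(seq(1.5, by = 0.73, length.out = n), 3),
             ambiguity = 1L, stringsAsFactors = FALSE)
}

test_that("both NMRStar dialects round-trip through the parser", {
  tab <- makeShiftTable()
  for (dialect in c("3.1", "2.1")) {
    f <- withr::local_tempfile(fileext = ".str")
    writeNMRStar(tab, f, dialect = dialect)
    p <- parseNMRStar(f)
    expect_equal(nrow(p$shifts), 12)
    expect_equal(sum(p$report$anomalies), 0)
    expect_equal(p$report$dialect, dialect)
    expect_equal(p$shifts$shift, tab$shift)
    expect_equal(p$shifts$residue_type, tab$residue_type)
    expect_equal(p$shifts$atom_name, tab$atom_name)
    expect_equal(p$conditions$temperature, 298)
    expect_equal(p$conditions$ph, 7)
    expect_equal(p$conditions$pressure, 1)
    expect_equal(p$conditions$solvent, "90% H2O/10% D2O")
    expect_equal(p$conditions$spectrometer, "AVANCE600")
  }
})

test_that("missing conditions come back as NA", {
  f <- withr::local_tempfile(fileext = ".str")
  writeNMRStar(makeShiftTable(), f,
               conditions = list(temperature = 300, ph = NA,
                                 pressure = NA, solvent = NA,
                                 spectrometer = NA))
  p <- parseNMRStar(f)
  expect_equal(p$conditions$temperature, 300)
  expect_true(is.na(p$conditions$pressure))
  expect_true(is.na(p$conditions$solvent))
})

test_that("a file without a shift loop is fatal", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_empty", "save_nothing",
               "   _Some.Tag value", "save_"), f)
  expect_error(parseNMRStar(f), "no chemical-shift loop")
  expect_error(parseNMRStar(file.path(tempdir(), "nonexistent.str")),
               "cannot read")
})

test_that("each corruption mode recovers with the documented behaviour", {
  tab <- makeShiftTable()
  base <- withr::local_tempfile(fileext = ".str")
  writeNMRStar(tab, base)
  p0 <- parseNMRStar(base)

  v <- withr::local_tempfile(fileext = ".str")
  corruptFile(base, "stray_token", v)
  p <- parseNMRStar(v)
  expect_equal(nrow(p$shifts), 12)
  expect_equal(unname(p$report$anomalies["stray_token"]), 1L)
  ## recovered values are bit-identical to the uncorrupted parse
  expect_identical(p$shifts$shift, p0$shifts$shift)

  corruptFile(base, "duplicate_frame", v)
  p <- parseNMRStar(v)
  expect_equal(nrow(p$shifts), 12)
  expect_equal(unname(p$report$anomalies["duplicate_frame"]), 1L)
  expect_identical(p$shifts$shift, p0$shifts$shift)

  corruptFile(base, "nonnumeric_shift", v)
  p <- parseNMRStar(v)
  expect_equal(nrow(p$shifts), 11)
  expect_equal(unname(p$report$anomalies["nonnumeric_shift"]), 1L)
  expect_identical(p$shifts$shift, p0$shifts$shift[-5])

  corruptFile(base, "dialect_v3_names", v)
  p <- parseNMRStar(v)
  expect_equal(nrow(p$shifts), 12)
  ## names differ on file but normalize back (see assignment tests)
  expect_identical(p$shifts$shift, p0$shifts$shift)

  expect_error(corruptFile(base, "no_such_mode", v))
})

test_that("duplicated shift rows keep the first occurrence and are counted", {
  tab <- makeShiftTable()
  tab2 <- rbind(tab, tab[3, ])
  f <- withr::local_tempfile(fileext = ".str")
  writeNMRStar(tab2, f)
  p <- parseNMRStar(f)
  expect_equal(nrow(p$shifts), 12)
  expect_equal(unname(p$report$anomalies["duplicate_row"]), 1L)
})
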