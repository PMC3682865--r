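test_that("fixture generation is byte-deterministic", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- fixtureSpec("AGSVLFKA", program = "mixed", sigma = 0.2,
                      seed = 9, id = "DET1")
  st <- buildStructure(spec, pdbPath = file.path(d1, "a.pdb"))
  buildStructure(spec, pdbPath = file.path(d2, "a.pdb"))
  expect_identical(readLines(file.path(d1, "a.pdb")),
                   readLines(file.path(d2, "a.pdb")))
  buildShifts(st, spec, starPath = file.path(d1, "a.str"))
  buildShifts(st, spec, starPath = file.path(d2, "a.str"))
  expect_identical(readLines(file.path(d1, "a.str")),
                   readLines(file.path(d2, "a.str")))
})

test_that("fixture specs validate their inputs", {
  expect_error(fixtureSpec("A"), "length >= 2")
  expect_error(fixtureSpec("AA", sigma = -1), "sigma")
  expect_error(fixtureSpec("AWA"), "unsupported fixture residue")
  expect_error(fixtureSpec("AAA", program = "custom"), "phi and psi")
})

test_that("structures re-parse from file within format precision", {
  spec <- fixtureSpec("AALSVKFAAL", program = "helix", id = "RP1")
  f <- withr::local_tempfile(fileext = ".pdb")
  st <- buildStructure(spec, pdbPath = f)
  st2 <- parsePDB(f)
  d <- max(abs(atoms(st)$x - atoms(st2)$x),
           abs(atoms(st)$y - atoms(st2)$y),
           abs(atoms(st)$z - atoms(st2)$z))
  expect_lt(d, 1e-3)
})

test_that("noise is seeded and additive on the deterministic part", {
  spec0 <- fixtureSpec("AALSVKFA", program = "helix", sigma = 0,
                       seed = 4, id = "NS1")
  st <- buildStructure(spec0)
  b0 <- buildShifts(st, spec0)
  expect_equal(b0$shifts$shift, b0$truth$deterministic)
  specN <- fixtureSpec("AALSVKFA", program = "helix", sigma = 0.3,
                       seed = 4, id = "NS1")
  b1 <- buildShifts(st, specN)
  b2 <- buildShifts(st, specN)
  expect_identical(b1$shifts$shift, b2$shifts$shift)
  resid <- b1$shifts$shift - b1$truth$deterministic
  expect_gt(sd(resid), 0.15); expect_lt(sd(resid), 0.5)
})

test_that("a uniform shift offset moves rmse but leaves corr unchanged", {
  ## re-referencing emulation at the metric level
  set.seed(6)
  e <- rnorm(40, 8, 1); p <- e + rnorm(40, 0, 0.2)
  base_rmse <- shiftRmse(e, p)
  expect_equal(shiftCorr(e + 1, p), shiftCorr(e, p), tolerance = 1e-12)
  expect_gt(shiftRmse(e + 1, p), base_rmse)
  expect_equal(shiftRmse(e + 1, p), sqrt(mean((e + 1 - p)^2)))
})

test_that("the fixture set covers all ten super classes", {
  study <- e2eStudy()
  r <- records(study$ds0)
  expect_setequal(unique(r$super_class),
                  classLabels(defaultSuperClassScheme()))
  ## ground truth of the generator matches the assembled records
  tr <- study$fx$truth[["FX01"]]
  sub <- r[r$pdb_id == "FX01", ]
  m <- merge(sub, tr, by = c("residue_index", "atom_name"))
  expect_gt(nrow(m), 0)
  expect_equal(m$experimental_shift, round(m$deterministic, 3),
               tolerance = 1e-9)
})
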