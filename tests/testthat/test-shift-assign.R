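buildPair <- function(sequence = "AALSVKFA", program = "helix",
                      id = "ASG1", sigma = 0) {
  spec <- fixtureSpec(sequence, program = program, id = id,
                      sigma = sigma)
  st <- buildStructure(spec)
  bs <- buildShifts(st, spec)
  list(structure = st, shifts = bs$shifts, truth = bs$truth)
}

test_that("chain matching pairs entities to best-aligning chains, ties first", {
  p <- buildPair()
  m <- matchChains(p$structure, p$shifts)
  expect_equal(m$chain_index, 1L)
  expect_equal(m$identity, 100)
  ## homodimer: duplicate the chain as chain_index 2; the first chain
  ## must win the tie
  a <- atoms(p$structure)
  b <- a; b$chain_id <- "B"; b$chain_index <- 2L; b$x <- b$x + 50
  dimer <- methods::initialize(p$structure, atoms = rbind(a, b))
  m <- matchChains(dimer, p$shifts)
  expect_equal(m$chain_index, 1L)
  ## entity matching only the second chain picks the second
  p2 <- buildPair(sequence = "GGVVLLKK", id = "ASG2")
  b2 <- atoms(p2$structure)
  b2$chain_id <- "B"; b2$chain_index <- 2L; b2$x <- b2$x + 50
  mixed <- methods::initialize(p$structure, atoms = rbind(a, b2))
  m2 <- matchChains(mixed, p2$shifts)
  expect_equal(m2$chain_index, 2L)
})

test_that("assignment attaches every shift once and conserves counts", {
  p <- buildPair()
  asg <- assignShifts(p$structure, p$shifts)
  expect_equal(nrow(asg$records), nrow(p$shifts))
  expect_equal(nrow(asg$unmatched), 0)
  key <- with(asg$records, paste(chain_index, residue_index, atom_name))
  expect_false(anyDuplicated(key) > 0)
  ## conservation under random row deletion from the structure
  a <- atoms(p$structure)
  drop <- which(a$atom_name == "HA")[1:2]
  thin <- methods::initialize(p$structure, atoms = a[-drop, ])
  asg2 <- assignShifts(thin, p$shifts)
  expect_equal(nrow(asg2$records) + nrow(asg2$unmatched), nrow(p$shifts))
  expect_equal(sum(asg2$unmatched$reason == "no atom"), 2)
})

test_that("a one-residue insertion on the shift side is re-anchored", {
  p <- buildPair(sequence = "AALSVKFAAL", id = "INS1")
  f <- withr::local_tempfile(fileext = ".str")
  writeNMRStar(p$shifts, f)
  v <- withr::local_tempfile(fileext = ".str")
  corruptFile(f, "one_residue_insertion", v)
  shifted <- parseNMRStar(v)$shifts
  asg <- assignShifts(p$structure, shifted)
  expect_equal(nrow(asg$unmatched), 0)
  ## every shift landed on the residue with its own residue type and
  ## the experimental values are preserved
  expect_equal(sort(asg$records$experimental_shift),
               sort(round(p$shifts$shift, 3)))
})

test_that("leading-digit names in the shift file normalize to the same records", {
  p <- buildPair(id = "DIA1")
  f <- withr::local_tempfile(fileext = ".str")
  writeNMRStar(p$shifts, f)
  v <- withr::local_tempfile(fileext = ".str")
  corruptFile(f, "dialect_v3_names", v)
  alt <- parseNMRStar(v)$shifts
  expect_false(identical(sort(alt$atom_name),
                         sort(p$shifts$atom_name)))
  a0 <- assignShifts(p$structure, parseNMRStar(f)$shifts)$records
  a1 <- assignShifts(p$structure, alt)$records
  o0 <- order(a0$residue_index, a0$atom_name)
  o1 <- order(a1$residue_index, a1$atom_name)
  expect_identical(a0$atom_name[o0], a1$atom_name[o1])
  expect_identical(a0$experimental_shift[o0], a1$experimental_shift[o1])
})
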