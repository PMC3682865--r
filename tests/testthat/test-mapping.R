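test_that("mapping files parse with comments and fail on bad lines", {
  m <- readMapping(text = "1ABC 4023\n2XYZ 4711")
  expect_equal(nrow(m), 2)
  expect_equal(m$pdb_id, c("1ABC", "2XYZ"))
  expect_equal(nrow(readMapping(text = "# only\n# comments")), 0)
  expect_error(readMapping(text = "1ABC 4023\n2XYZ"),
               "malformed mapping line 2")
})

test_that("the perfect-alignment filter keeps exactly identity-100 entries", {
  e <- data.frame(pdb_id = c("A", "B", "C"),
                  alignment_identity = c(100, 99.5, 100))
  kept <- filterPerfectAlignment(e)
  expect_equal(kept$pdb_id, c("A", "C"))
  expect_equal(nrow(filterPerfectAlignment(e[0, , drop = FALSE])), 0)
  ## a gapped alignment cannot reach 100 under the columns definition
  id <- globalAlign("MKVA", "MKVLA")$identity
  expect_lt(id, 100)
})

test_that("greedy culling is sound and near-optimal on small sets", {
  expect_equal(length(cullHomologs(c(a = "AAAAAAAA", b = "AAAAAAAA"))), 1)
  two <- c(x = "AAAAAAAAAACCCCCCCCCC", y = "WWWWWWWWWWYYYYYYYYYY")
  expect_equal(length(cullHomologs(two, cutoff = 10)), 2)
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    seqs <- vapply(seq_len(n), function(i) randomSeq(sample(6:12, 1)),
                   "")
    names(seqs) <- paste0("s", seq_len(n))
    cutoff <- sample(c(10, 25, 40), 1)
    kept <- cullHomologs(seqs, cutoff)
    ## soundness: no retained pair above the cutoff
    if (length(kept) > 1) {
      pr <- utils::combn(kept, 2)
      for (k in seq_len(ncol(pr)))
        expect_lte(alignmentIdentity(seqs[[pr[1, k]]], seqs[[pr[2, k]]]),
                   cutoff)
    }
    ## near-optimality: within one of the brute-force maximum
    idMat <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      if (i == j) 100 else alignmentIdentity(seqs[[i]], seqs[[j]])))
    expect_gte(length(kept), bruteForceCullCount(idMat, cutoff) - 1)
  }
})

test_that("culling is deterministic longest-first", {
  seqs <- c(short = "AAAA", long = "AAAAAAAAAAAA")
  expect_equal(cullHomologs(seqs, cutoff = 10), "long")
})

test_that("type-1 filters compose order-independently", {
  e <- data.frame(pdb_id = sprintf("P%d", 1:4),
                  alignment_identity = c(100, 99, 100, 100),
                  stringsAsFactors = FALSE)
  meta <- list(P1 = list(polymers = "protein", het = character(0)),
               P2 = list(polymers = "protein", het = character(0)),
               P3 = list(polymers = c("protein", "dna"), het = character(0)),
               P4 = list(polymers = "protein", het = "HEM"))
  protOK <- vapply(e$pdb_id, function(id)
    filterProteinOnly(e[e$pdb_id == id, ], meta[[id]])$keep, logical(1))
  aThenB <- filterPerfectAlignment(e[protOK, , drop = FALSE])$pdb_id
  alnOK <- filterPerfectAlignment(e)
  bThenA <- alnOK$pdb_id[vapply(alnOK$pdb_id, function(id)
    filterProteinOnly(alnOK[alnOK$pdb_id == id, ], meta[[id]])$keep,
    logical(1))]
  expect_identical(aThenB, bThenA)
  expect_identical(aThenB, "P1")
})

test_that("the protein-only filter drops nucleic polymers and ligands", {
  e <- data.frame(pdb_id = "1ABC")
  expect_true(filterProteinOnly(e, list(polymers = "protein",
                                        het = "HOH"))$keep)
  r <- filterProteinOnly(e, list(polymers = c("protein", "dna"),
                                 het = character(0)))
  expect_false(r$keep); expect_match(r$reason, "nucleic")
  r <- filterProteinOnly(e, list(polymers = "protein", het = "HEM"))
  expect_false(r$keep); expect_match(r$reason, "ligand")
  r <- filterProteinOnly(e, NULL)
  expect_true(r$keep); expect_match(r$reason, "undetermined")
})

test_that("the energy filter applies the cutoff inclusively", {
  registerScorer("fixed500", function(s) 500)
  registerScorer("fixed1500", function(s) 1500)
  registerScorer("fixed1000", function(s) 1000)
  registerScorer("broken", function(s) stop("boom"))
  st <- isolatedAtomStructure()
  expect_true(filterEnergy(st, scorer = "fixed500")$keep)
  expect_false(filterEnergy(st, scorer = "fixed1500")$keep)
  expect_true(filterEnergy(st, scorer = "fixed1000")$keep)
  r <- filterEnergy(st, scorer = "broken")
  expect_false(r$keep); expect_match(r$reason, "unscorable")
  expect_error(getScorer("no-such-scorer"), "unknown structure-quality")
})
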