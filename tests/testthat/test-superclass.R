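test_that("the default scheme has 10 disjoint classes with the published vocabulary", {
  sc <- defaultSuperClassScheme()
  expect_equal(length(classLabels(sc)), 10)
  expect_setequal(classLabels(sc),
                  c("N", "CA", "CB", "C", "H", "HA", "HB", "HD", "HG",
                    "HEHZ"))
  all_names <- unlist(lapply(classLabels(sc), classMembers, x = sc))
  expect_false(anyDuplicated(all_names) > 0)
  expect_setequal(classMembers(sc, "HA"), c("HA", "1HA", "2HA"))
  expect_setequal(classMembers(sc, "HD"),
                  c("2HD", "HD1", "HD2", "1HD1", "1HD2", "2HD2"))
})

test_that("assignment reproduces the published name-to-class pairs", {
  expect_identical(assignSuperClass("CA", "ALA"), "CA")
  expect_identical(assignSuperClass("2HD2", "LEU"), "HD")
  expect_identical(assignSuperClass("HZ3", "LYS"), "HEHZ")
  expect_identical(assignSuperClass("HD22", "LEU"), "HD")  # = 2HD2
  expect_identical(assignSuperClass("N", "GLY"), "N")
  expect_identical(assignSuperClass("H", "VAL"), "H")
  ## unlisted names map to no class
  expect_true(is.na(assignSuperClass("O", "ALA")))
  expect_true(is.na(assignSuperClass("CG", "LEU")))
  expect_true(is.na(assignSuperClass("HB3", "ALA")))  # 3HB unlisted
})

test_that("assignment over a dataset is a partition", {
  st <- buildStructure(fixtureSpec("AGSVLFK", program = "extended",
                                   id = "PART1"))
  a <- atoms(st)
  cls <- assignSuperClasses(a)
  counts <- table(cls, useNA = "always")
  expect_equal(sum(counts), nrow(a))
})

test_that("auto clustering respects element segregation and class counts", {
  counts <- c(H = 500, H1 = 400, HC = 450, CT = 600, CX = 550, N = 300)
  elems <- c(H = "H", H1 = "H", HC = "H", CT = "C", CX = "C", N = "N")
  sc3 <- autoClusterScheme(counts, elems, nClasses = 3)
  expect_equal(length(classLabels(sc3)), 3)
  for (lbl in classLabels(sc3)) {
    mem <- classMembers(sc3, lbl)
    expect_equal(length(unique(elems[mem])), 1, label = lbl)
  }
  sc6 <- autoClusterScheme(counts, elems, nClasses = 6)
  expect_equal(length(classLabels(sc6)), 6)
  expect_error(autoClusterScheme(counts, elems, nClasses = 7),
               "fewer atom types")
  ## a rare type is merged into the nearest-name abundant class of its
  ## element rather than keeping its own class
  counts2 <- c(HA = 1000, HB = 900, HX = 10, CT = 800)
  elems2 <- c(HA = "H", HB = "H", HX = "H", CT = "C")
  sc <- autoClusterScheme(counts2, elems2, nClasses = 3)
  merged <- Filter(function(l) "HX" %in% classMembers(sc, l),
                   classLabels(sc))
  expect_length(merged, 1)
  expect_gt(length(classMembers(sc, merged)), 1)
  ## brute-force check: among the two possible merges of HX, the
  ## greedy nearest-name rule picks one that keeps sizes legal
  expect_true(all(c("HB", "HX") %in% classMembers(sc, merged)) ||
              all(c("HA", "HX") %in% classMembers(sc, merged)))
})

test_that("schemes serialize to text and back", {
  sc <- defaultSuperClassScheme()
  f <- withr::local_tempfile(fileext = ".txt")
  writeScheme(sc, f)
  sc2 <- readScheme(f)
  expect_equal(classLabels(sc2), classLabels(sc))
  for (lbl in classLabels(sc))
    expect_equal(classMembers(sc2, lbl), classMembers(sc, lbl))
})
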