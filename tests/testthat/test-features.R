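test_that("the feature registry resolves names and rejects unknowns", {
  expect_type(featureRegistry("ring_current")$fn, "closure")
  expect_error(featureRegistry("no_such_feature"), "unknown feature")
  registerFeature("user_test_feature", "numeric",
                  function(s, ctx) rep(1, nrow(atoms(s))))
  expect_identical(featureRegistry("user_test_feature")$kind, "numeric")
  expect_error(registerFeature("user_test_feature", "numeric",
                               function(s, ctx) 1),
               "already registered")
})

test_that("random-coil lookups are pure table reads with missing-entry errors", {
  expect_error(randomCoilShift("GLY", "CB"), "GLY.*CB|CB.*GLY")
  expect_equal(randomCoilShift("ALA", "CA"), 52.5)
  expect_equal(randomCoilShift("GLY", "HA2"), randomCoilShift("GLY", "HA"))
  ## double-entry transcription check against an independently
  ## re-typed sample of the published random-coil values
  retyped <- rbind(
    ALA = c(H = 8.24, HA = 4.32, CA = 52.5, CB = 19.1, C = 177.8, N = 123.8),
    GLY = c(H = 8.33, HA = 3.96, CA = 45.1, CB = NA, C = 174.9, N = 108.8),
    LEU = c(H = 8.16, HA = 4.34, CA = 55.1, CB = 42.4, C = 177.6, N = 121.8),
    SER = c(H = 8.31, HA = 4.47, CA = 58.3, CB = 63.8, C = 174.6, N = 115.7),
    TRP = c(H = 8.25, HA = 4.66, CA = 57.5, CB = 29.6, C = 176.1, N = 121.3),
    VAL = c(H = 8.03, HA = 4.12, CA = 62.2, CB = 32.9, C = 176.3, N = 119.2))
  for (res in rownames(retyped))
    for (atom in colnames(retyped)) {
      if (is.na(retyped[res, atom])) next
      expect_equal(randomCoilShift(res, atom), retyped[[res, atom]],
                   label = paste(res, atom))
    }
})

test_that("ring current follows the point-dipole form", {
  rings <- list(list(centroid = c(0, 0, 0), normal = c(0, 0, 1),
                     intensity = 1))
  ## magic angle: 1 - 3cos^2(theta) = 0
  th <- acos(sqrt(1 / 3))
  expect_equal(ringCurrentShift(4 * c(sin(th), 0, cos(th)), rings), 0,
               tolerance = 1e-12)
  ## exact r^-3 on the ring axis
  expect_equal(ringCurrentShift(c(0, 0, 3), rings) /
               ringCurrentShift(c(0, 0, 6), rings), 8)
  ## shielding above the ring, deshielding in the plane
  expect_lt(ringCurrentShift(c(0, 0, 3), rings), 0)
  expect_gt(ringCurrentShift(c(3, 0, 0), rings), 0)
  expect_error(ringCurrentShift(c(0, 0, 0.2), rings), "0.5 A")
})

test_that("electric-field term has its closed one-source forms", {
  ## H bonded to N at origin, bond along +x; source on the axis
  mk <- function(srcPos, srcName = "NZ") structureFromCoords(data.frame(
    atom_name = c("N", "H", srcName),
    element = c("N", "H", substr(srcName, 1, 1)),
    residue_index = c(1L, 1L, 2L), residue_seq = c(1L, 1L, 2L),
    x = c(0, 1.0, srcPos[1]), y = c(0, 0, srcPos[2]),
    z = c(0, 0, srcPos[3])))
  q <- ShiftForge:::.PARTIAL_CHARGES[["NZ"]]
  r <- 3
  st <- mk(c(1 + r, 0, 0))
  expect_equal(electricFieldShift(st, 2, charges = c(NZ = q)),
               q / r^2, tolerance = 1e-12)
  ## source perpendicular to the bond axis contributes nothing
  st <- mk(c(1, r, 0))
  expect_equal(electricFieldShift(st, 2, charges = c(NZ = q)), 0,
               tolerance = 1e-12)
  ## two symmetric charges: transverse components cancel, axial add
  st2 <- structureFromCoords(data.frame(
    atom_name = c("N", "H", "NZ", "NZ"),
    element = c("N", "H", "N", "N"),
    residue_index = c(1L, 1L, 2L, 3L), residue_seq = c(1L, 1L, 2L, 3L),
    x = c(0, 1, 4, 4), y = c(0, 0, 2, -2), z = 0))
  one <- q * (3 / sqrt(13)) / 13
  expect_equal(electricFieldShift(st2, 2, charges = c(NZ = q)), 2 * one,
               tolerance = 1e-12)
  ## an unbonded atom is not a valid target
  expect_error(electricFieldShift(st2, 3), "exactly one covalent bond")
})

test_that("hydrogen-bond term is thresholded and monotone", {
  mk <- function(r) structureFromCoords(data.frame(
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_index = c(1L, 1L, 5L), residue_seq = c(1L, 1L, 5L),
    x = c(0, 1.0, 1.0 + r), y = 0, z = 0))
  expect_equal(hbondEffectShift(mk(5), 2), 0)
  r0 <- (19.2 / 2.3)^(1 / 3)
  expect_equal(hbondEffectShift(mk(r0), 2), 0, tolerance = 1e-12)
  expect_gt(hbondEffectShift(mk(1.8), 2), hbondEffectShift(mk(2.2), 2))
})

test_that("torsions recover programmed dihedrals and handle termini", {
  ## constructed four-atom chains
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(dihedralAngle(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0)
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(dihedralAngle(trans[1, ], trans[2, ], trans[3, ],
                                 trans[4, ])), 180)
  spec <- fixtureSpec(paste(rep("A", 12), collapse = ""),
                      program = "helix", id = "TOR1")
  st <- buildStructure(spec)
  tors <- torsionAngles(st)
  expect_true(is.na(tors$phi[1]))
  expect_true(is.na(tors$psi[nrow(tors)]))
  expect_lt(max(abs(tors$phi[-1] + 57)), 1e-6)
  expect_lt(max(abs(tors$psi[-nrow(tors)] + 47)), 1e-6)
  ## independent oracle: bio3d's torsion computation on the same file
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(st, f)
  bt <- bio3d::torsion.pdb(bio3d::read.pdb(f))
  expect_equal(unname(bt$phi[-1]), tors$phi[-1][seq_along(bt$phi[-1])],
               tolerance = 1e-3)
})

test_that("secondary structure labels helices and leaves short/extended coil", {
  hel <- buildStructure(fixtureSpec(strrep("A", 12), program = "helix",
                                    id = "SS1"))
  ss <- secondaryStructure(hel)
  expect_true(all(ss$ss[4:9] == "helix"))
  ext <- buildStructure(fixtureSpec(strrep("A", 12),
                                    program = "extended", id = "SS2"))
  expect_false(any(secondaryStructure(ext)$ss == "helix"))
  two <- buildStructure(fixtureSpec("AA", program = "extended",
                                    id = "SS3"))
  expect_true(all(secondaryStructure(two)$ss == "coil"))
  ## oracle: helix fixtures have i -> i+4 amide-to-carbonyl bonds
  hb <- detectHBonds(hel)
  a <- atoms(hel)
  sep <- a$residue_index[hb$hIdx] - a$residue_index[hb$acceptorIdx]
  expect_true(any(sep == 4))
})

test_that("surface areas match the closed form and symmetry", {
  iso <- isolatedAtomStructure("C")
  sas <- solventAccessibleSurface(iso)
  expect_equal(sas$atom, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  expect_equal(sas$residue, sas$atom)
  ## atom caged by neighbours is buried
  cage <- expand.grid(x = c(-2, 2), y = c(-2, 2), z = c(-2, 2))
  caged <- structureFromCoords(data.frame(
    atom_name = c("C", rep("C", 8)), element = "C",
    residue_index = 1L, residue_seq = 1L,
    x = c(0, cage$x), y = c(0, cage$y), z = c(0, cage$z)))
  expect_lt(solventAccessibleSurface(caged)$atom[1], 2)
  ## two identical overlapping atoms have equal areas
  twin <- structureFromCoords(data.frame(
    atom_name = c("C", "C"), element = "C", residue_index = c(1L, 2L),
    residue_seq = c(1L, 2L), x = c(0, 1.0), y = 0, z = 0))
  s2 <- solventAccessibleSurface(twin)
  expect_equal(s2$atom[1], s2$atom[2], tolerance = 1e-9)
  expect_error(solventAccessibleSurface(isolatedAtomStructure("ZZ")),
               "radius")
})

test_that("atomic density counts heavy atoms in the sphere", {
  expect_equal(atomicDensity(isolatedAtomStructure(), 1), 0L)
  tri <- structureFromCoords(data.frame(
    atom_name = c("C", "C", "C", "C", "H"), element = c("C", "C", "C", "C", "H"),
    residue_index = 1:5, residue_seq = 1:5,
    x = c(0, 4, 0, 0, 1), y = c(0, 0, 4, 0, 0), z = c(0, 0, 0, 4, 0)))
  expect_equal(atomicDensity(tri, 1, radius = 5), 3L)
  xyz <- as.matrix(atoms(tri)[, c("x", "y", "z")])
  rot <- rigidTransform(xyz, axis = c(1, 1, 0), angleDeg = 71,
                        translation = c(3, -2, 9))
  a2 <- atoms(tri); a2$x <- rot[, 1]; a2$y <- rot[, 2]; a2$z <- rot[, 3]
  expect_equal(atomicDensity(structureFromCoords(a2), 1, radius = 5), 3L)
})

test_that("hydrogen and disulfide bonds follow the geometric criteria", {
  ## N-H...O built at 1.9 A / 165 degrees
  ang <- (180 - 165) * pi / 180
  hb <- structureFromCoords(data.frame(
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_index = c(1L, 1L, 5L), residue_seq = c(1L, 1L, 5L),
    x = c(0, 1, 1 + 1.9 * cos(ang)), y = c(0, 0, 1.9 * sin(ang)), z = 0))
  expect_equal(nrow(detectHBonds(hb)), 1)
  far <- structureFromCoords(data.frame(
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_index = c(1L, 1L, 5L), residue_seq = c(1L, 1L, 5L),
    x = c(0, 1, 5), y = 0, z = 0))
  expect_equal(nrow(detectHBonds(far)), 0)
  ss <- structureFromCoords(data.frame(
    atom_name = c("SG", "SG"), element = c("S", "S"),
    residue_type = "CYS", residue_index = c(1L, 8L),
    residue_seq = c(1L, 8L), x = c(0, 2.05), y = 0, z = 0))
  expect_equal(nrow(detectDisulfides(ss)), 1)
})

test_that("backbone distances reproduce construction and handle termini", {
  st <- buildStructure(fixtureSpec("AAA", program = "extended",
                                   id = "BD1"))
  bd <- backboneDistances(st)
  expect_equal(bd$dist_N_CA, rep(1.458, 3), tolerance = 1e-9)
  expect_equal(bd$dist_CA_C, rep(1.525, 3), tolerance = 1e-9)
  expect_true(is.na(bd$dist_CA_CA_prev[1]))
  expect_true(is.na(bd$dist_CA_CA_next[3]))
  expect_equal(bd$dist_CA_CA_prev[2], bd$dist_CA_CA_next[1])
})

test_that("geometric features are rigid-motion invariant and deterministic", {
  spec <- fixtureSpec("AAFSVKLA", program = "helix", id = "INV1")
  st <- buildStructure(spec)
  geo <- c("phi", "psi", "chi1", "secondary_structure", "dist_N_CA",
           "dist_CA_C", "atom_sas", "residue_sas", "atomic_density",
           "has_hbond", "ring_current", "hbond_effect")
  f1 <- computeFeatureTable(st, geo)
  f1b <- computeFeatureTable(st, geo)
  expect_identical(f1, f1b)   # bit-identical recomputation
  xyz <- as.matrix(atoms(st)[, c("x", "y", "z")])
  rot <- rigidTransform(xyz, axis = c(1, 2, 3), angleDeg = 123.4,
                        translation = c(-7, 11, 5))
  a2 <- atoms(st); a2$x <- rot[, 1]; a2$y <- rot[, 2]; a2$z <- rot[, 3]
  st2 <- methods::initialize(st, atoms = a2)
  f2 <- computeFeatureTable(st2, geo)
  angles <- c("phi", "psi", "chi1")
  for (col in geo) {
    ref <- f1[[col]]; got <- f2[[col]]
    if (col %in% angles) {
      idx <- !is.na(ref)
      expect_true(all(is.na(ref) == is.na(got)), label = col)
      expect_lt(max(angDiff(got[idx], ref[idx])), 1e-6)
    } else if (is.numeric(ref)) {
      expect_equal(got, ref, tolerance = 1e-6, label = col)
    } else expect_identical(got, ref)
  }
  ## distant-ring decay: r^-3 puts a 50 A ring below a millippm and a
  ## 500 A ring below a micro-ppm (B = 30.42 ppm A^3)
  rings <- list(list(centroid = c(50, 0, 0), normal = c(0, 0, 1),
                     intensity = 1))
  expect_lt(abs(ringCurrentShift(c(0, 0, 0), rings)), 1e-3)
  rings[[1]]$centroid <- c(500, 0, 0)
  expect_lt(abs(ringCurrentShift(c(0, 0, 0), rings)), 1e-6)
})

test_that("feature vectors are complete with explicit missing markers", {
  st <- buildStructure(fixtureSpec("AGSA", program = "extended",
                                   id = "CMP1"))
  ft <- computeFeatureTable(st)   # full default definition, empty context
  expect_setequal(names(ft), defaultFeatureDefinition())
  expect_equal(nrow(ft), nrow(atoms(st)))
  expect_identical(unique(ft$solvent), "missing")
  expect_true(all(is.na(ft$temperature)))   # numeric missing stays NA
  expect_true(all(is.na(ft$phi[atoms(st)$residue_index == 1])))
})
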