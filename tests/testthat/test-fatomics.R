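# cylinder-like phantom: an annular EAT band of uniform in-plane thickness
cylinderPhantom <- function(seed = 1L, shellRho = 0.5) {
  generatePhantom(phantomSpec(
    gridShape = c(48L, 48L, 12L), voxelSpacing = c(0.5, 0.5, 3),
    pericardiumSemiAxes = c(10, 10, 4000), eatShellRho = shellRho,
    eatFraction = 1, seed = seed))
}

spherePhantom <- function(seed = 1L) {
  generatePhantom(phantomSpec(
    gridShape = c(44L, 44L, 44L), voxelSpacing = c(0.8, 0.8, 0.8),
    pericardiumSemiAxes = c(16, 16, 16), eatShellRho = 0.5,
    eatFraction = 1, seed = seed))
}

test_that("slabs split the occupied slice range into four equal bands", {
  ph <- cylinderPhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  z <- geo@voxelIndex[, 3]
  expect_equal(sort(unique(z)), 1:12)       # EAT occupies all 12 slices
  perSlab <- split(z, geo@slab)
  expect_equal(lapply(perSlab, function(s) sort(unique(s))),
               list(`1` = 1:3, `2` = 4:6, `3` = 7:9, `4` = 10:12))
  expect_equal(sum(lengths(perSlab)), nrow(geo@voxelIndex))
})

test_that("every EAT voxel gets exactly one slab and one ribbon", {
  ph <- spherePhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  n <- nrow(geo@voxelIndex)
  expect_length(geo@slab, n)
  expect_length(geo@ribbon, n)
  expect_true(all(geo@slab %in% 1:4))
  expect_true(all(geo@ribbon %in% 1:5))
})

test_that("on a spherical shell, ribbon populations shrink outward to inward", {
  ph <- spherePhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  counts <- tabulate(geo@ribbon, 5)
  expect_true(all(diff(counts) < 0))
  expect_equal(which.max(counts), 1L)
})

test_that("geometry preconditions are enforced", {
  ph <- cylinderPhantom()
  empty <- RegionMask(array(FALSE, dim(ph$eat@mask)), ph$eat@spacing, "eat")
  expect_error(assignSlabsRibbons(empty, ph$pericardium), "empty")
  outside <- ph$eat
  outside@mask[1, 1, 1] <- TRUE             # a voxel outside the pericardium
  expect_error(assignSlabsRibbons(outside, ph$pericardium), "contained")
})

test_that("ribbon probability features are exact bin fractions", {
  ph <- cylinderPhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  vol <- ph$volume
  r3 <- which(geo@ribbon == 3)
  expect_gt(length(r3), 4)
  # plant an exact 25% point mass in [-150, -130) within ribbon 3
  n3 <- length(r3)
  k <- floor(n3 / 4)
  vox <- geo@voxelIndex[r3, , drop = FALSE]
  vol@hu[vox] <- -80
  vol@hu[vox[seq_len(k), , drop = FALSE]] <- -140
  fv <- extractFeatures(vol, geo)
  expect_equal(unname(fv["SR3_Pro_150_130"]), k / n3, tolerance = 1e-12)
  # point mass: every ribbon-4 voxel at -80 HU
  vol2 <- ph$volume
  vox4 <- geo@voxelIndex[geo@ribbon == 4, , drop = FALSE]
  vol2@hu[vox4] <- -80
  fv2 <- extractFeatures(vol2, geo)
  expect_equal(unname(fv2["SR4_Pro_90_70"]), 1)
  otherBins <- grep("^SR4_Pro_", names(fv2), value = TRUE)
  expect_equal(sum(fv2[otherBins]), 1)      # all mass in the one bin
})

test_that("probabilities normalize within every nonempty ribbon and slab", {
  for (seed in c(1, 2)) {
    ph <- spherePhantom(seed)
    geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
    fv <- extractFeatures(ph$volume, geo)
    for (k in 1:5)
      expect_equal(sum(fv[grep(sprintf("^SR%d_Pro_", k), names(fv))]), 1,
                   tolerance = 1e-12)
    for (k in 1:4)
      expect_equal(sum(fv[grep(sprintf("^SS%d_Pro_", k), names(fv))]), 1,
                   tolerance = 1e-12)
  }
})

test_that("an empty ribbon yields zero features and a warning", {
  ph <- cylinderPhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  geo@ribbon[geo@ribbon == 2L] <- 1L        # artificially empty ribbon 2
  expect_warning(fv <- extractFeatures(ph$volume, geo), "ribbon 2")
  expect_true(all(fv[grep("^SR2_Pro_", names(fv))] == 0))
})

test_that("a single ribbon reproduces the whole-EAT histogram features", {
  ph <- cylinderPhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium, nRibbons = 1)
  fv <- extractFeatures(ph$volume, geo)
  whole <- fv[grep("^Pro_", names(fv))]
  sr1 <- fv[grep("^SR1_Pro_", names(fv))]
  expect_equal(unname(sr1), unname(whole))
})

test_that("EAT volume is voxel count times voxel volume", {
  mask <- array(FALSE, c(20, 20, 10))
  mask[3:12, 3:12, 1:10] <- TRUE            # exactly 1000 voxels
  peri <- RegionMask(array(TRUE, dim(mask)), c(0.5, 0.5, 3), "pericardium")
  eat <- RegionMask(mask, c(0.5, 0.5, 3), "eat")
  geo <- assignSlabsRibbons(eat, peri)
  vol <- CTVolume(array(-100, dim(mask)), c(0.5, 0.5, 3))
  fv <- suppressWarnings(extractFeatures(vol, geo))
  expect_equal(unname(fv["eat_volume_mm3"]), 1000 * 0.5 * 0.5 * 3)
})

test_that("skewness of a symmetric HU distribution is near zero", {
  ph <- cylinderPhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  vol <- ph$volume
  n <- nrow(geo@voxelIndex)
  sym <- rep(c(-120, -80), length.out = n)  # exactly symmetric around -100
  vol@hu[geo@voxelIndex] <- sym
  fv <- extractFeatures(vol, geo)
  expect_lt(abs(unname(fv["eat_skewness"])), 0.02)
})

test_that("features are invariant under rigid voxel translation", {
  ph <- generatePhantom(phantomSpec(
    gridShape = c(32L, 32L, 10L), voxelSpacing = c(1, 1, 3),
    pericardiumCenter = c(12, 12, 12), pericardiumSemiAxes = c(9, 9, 10),
    eatShellRho = 0.6, eatFraction = 1, seed = 4L))
  shift <- c(4L, 5L, 2L)
  shiftArr <- function(a, fill) {
    out <- array(fill, dim(a))
    d <- dim(a)
    out[(1 + shift[1]):d[1], (1 + shift[2]):d[2], (1 + shift[3]):d[3]] <-
      a[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:(d[3] - shift[3])]
    out
  }
  volT <- CTVolume(shiftArr(ph$volume@hu, 40), ph$volume@spacing)
  eatT <- RegionMask(shiftArr(ph$eat@mask, FALSE), ph$eat@spacing, "eat")
  periT <- RegionMask(shiftArr(ph$pericardium@mask, FALSE),
                      ph$pericardium@spacing, "pericardium")
  fv <- extractFeatures(ph$volume,
                        assignSlabsRibbons(ph$eat, ph$pericardium))
  fvT <- extractFeatures(volT, assignSlabsRibbons(eatT, periT))
  # thickness comes from sampled ray casting: rounding at cell boundaries can
  # flip single samples under translation, so allow a hundredth of a mm there
  thick <- grep("thickness", names(fv))
  expect_equal(fv[-thick], fvT[-thick], tolerance = 1e-10)
  expect_equal(fv[thick], fvT[thick], tolerance = 0.01)
})

test_that("spacing rescaling scales only the mm-valued features", {
  ph <- cylinderPhantom()
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  fv <- extractFeatures(ph$volume, geo)
  vol2 <- CTVolume(ph$volume@hu, ph$volume@spacing * 2)
  eat2 <- RegionMask(ph$eat@mask, ph$eat@spacing * 2, "eat")
  peri2 <- RegionMask(ph$pericardium@mask, ph$pericardium@spacing * 2,
                      "pericardium")
  fv2 <- extractFeatures(vol2, assignSlabsRibbons(eat2, peri2))
  expect_equal(unname(fv2["eat_volume_mm3"]),
               8 * unname(fv["eat_volume_mm3"]))
  for (nm in grep("principal_axis|thickness", names(fv), value = TRUE))
    expect_equal(unname(fv2[nm]), 2 * unname(fv[nm]), tolerance = 1e-8)
  probNames <- grep("Pro_", names(fv), value = TRUE)
  expect_equal(fv2[probNames], fv[probNames], tolerance = 1e-10)
})

test_that("fat thickness recovers a uniform 5 mm band within a voxel", {
  ph <- cylinderPhantom()                  # 10 mm radius, band 5 mm thick
  geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
  th <- fatThickness(geo)
  expect_lt(abs(th["mean_mm"] - 5), 0.5)
  expect_lt(abs(th["max_mm"] - 5), 0.5)
})

test_that("a single EAT voxel degenerates to the in-plane extent", {
  mask <- array(FALSE, c(10, 10, 4))
  mask[5, 5, 2] <- TRUE
  peri <- RegionMask(array(TRUE, dim(mask)), c(0.5, 0.5, 3), "pericardium")
  eat <- RegionMask(mask, c(0.5, 0.5, 3), "eat")
  geo <- assignSlabsRibbons(eat, peri)
  th <- fatThickness(geo)
  expect_equal(unname(th["mean_mm"]), 0.5)
  expect_equal(unname(th["max_mm"]), 0.5)
})

test_that("the feature schema is stable across inputs", {
  fvA <- extractFeatures(cylinderPhantom(1)$volume,
                         assignSlabsRibbons(cylinderPhantom(1)$eat,
                                            cylinderPhantom(1)$pericardium))
  phB <- spherePhantom(2)
  fvB <- extractFeatures(phB$volume,
                         assignSlabsRibbons(phB$eat, phB$pericardium))
  expect_identical(names(fvA), names(fvB))
  # the three families are present
  expect_true(all(c("eat_volume_mm3", "eat_thickness_mean_mm") %in% names(fvA)))
  expect_true(all(c("eat_min_hu", "eat_max_hu", "eat_mean_hu",
                    "eat_skewness") %in% names(fvA)))
  expect_true(any(grepl("^SR[1-5]_Pro_", names(fvA))))
  expect_true(any(grepl("^SS[1-4]_Pro_", names(fvA))))
  # named features of the published importance ranking exist in the schema
  expect_true(all(c("SR4_Pro_90_70", "SR3_Pro_170_150", "SR3_Pro_150_130")
                  %in% names(fvA)))
})
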