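test_that("a 10 mm^2 component peaking at 450 HU on a 3 mm slice scores 40", {
  hu <- matrix(0, 20, 20)
  hu[3:12, 5:8] <- 200          # 40 voxels at 0.5 x 0.5 mm -> 10 mm^2
  hu[5, 6] <- 450
  vol <- sliceVolume(hu)
  les <- findLesions(vol, fullMask(vol))
  expect_equal(nrow(les), 1L)
  expect_equal(les$voxel_count, 40L)
  expect_equal(les$area_mm2, 10)
  expect_equal(les$weight, 4L)
  expect_equal(les$score, 40)
})

test_that("sub-threshold gaps split lesions without changing the total", {
  hu <- matrix(0, 20, 20)
  hu[2:4, 2:4] <- 300
  hu[2:4, 8:10] <- 300          # separated by sub-threshold voxels
  vol <- sliceVolume(hu)
  les <- findLesions(vol, fullMask(vol))
  expect_equal(nrow(les), 2L)
  merged <- hu
  merged[2:4, 5:7] <- 300       # bridge the gap at the same weight
  lesM <- findLesions(sliceVolume(merged), fullMask(vol))
  expect_equal(nrow(lesM), 1L)
  # additivity of area x weight: merging at equal weight adds the bridge only
  expect_equal(sum(les$score) + 9 * 0.25 * 3, sum(lesM$score))
})

test_that("components below the minimum lesion area are discarded", {
  hu <- matrix(0, 10, 10)
  hu[5, 5] <- 400               # 0.25 mm^2 < 1 mm^2
  vol <- sliceVolume(hu)
  expect_equal(nrow(findLesions(vol, fullMask(vol))), 0L)
  expect_equal(nrow(findLesions(vol, fullMask(vol), minAreaMm2 = 0.2)), 1L)
})

test_that("all-sub-threshold territories yield an empty lesion list", {
  hu <- matrix(129.9, 8, 8)
  vol <- sliceVolume(hu)
  expect_equal(nrow(findLesions(vol, fullMask(vol))), 0L)
})

test_that("mask/volume misalignment is an error", {
  vol <- sliceVolume(matrix(0, 8, 8))
  bad <- RegionMask(array(TRUE, c(9, 8, 1)), vol@spacing, "LAD")
  expect_error(findLesions(vol, bad), "aligned")
})

test_that("engine total matches the brute-force voxel oracle", {
  for (seed in 1:10) {
    ph <- randomLesionPhantom(seed)
    panel <- scoreVolume(ph$volume, ph$territories)
    oracle <- bruteForceAgatston(ph$volume@hu, ph$territories$LAD@mask,
                                 ph$volume@spacing)
    expect_equal(panel@total, oracle, tolerance = 1e-10,
                 label = sprintf("engine total (seed %d)", seed))
  }
})

test_that("raising voxel HU or adding lesions never lowers the total", {
  ph <- randomLesionPhantom(42)
  base <- scoreVolume(ph$volume, ph$territories)@total
  raised <- ph$volume
  idx <- which(ph$territories$LAD@mask & raised@hu >= 130)[1:5]
  raised@hu[idx] <- raised@hu[idx] + 300
  expect_gte(scoreVolume(raised, ph$territories)@total, base)
  # a new supra-threshold voxel block can only add score
  added <- ph$volume
  added@hu[2:4, 2:4, 2] <- 500
  expect_gte(scoreVolume(added, ph$territories)@total, base)
})

test_that("per-vessel scores aggregate into the published panel", {
  panel <- scorePanel(c(LM = 43, LAD = 1168, LCX = 633, RCA = 1183))
  expect_identical(panel@total, 3027)
  expect_true(panel@highCac)
  expect_equal(panel@diffusivity, 1 - 1183 / 3027, tolerance = 1e-12)
  expect_equal(unname(panel@logScores["LAD"]), log10(1169), tolerance = 1e-12)
})

test_that("degenerate panels honour the score-panel invariants", {
  zero <- scorePanel(c(LM = 0, LAD = 0, LCX = 0, RCA = 0))
  expect_identical(zero@total, 0)
  expect_true(all(zero@logScores == 0))
  expect_identical(zero@diffusivity, 0)
  expect_false(zero@highCac)
  one <- scorePanel(c(LAD = 500))          # missing arteries score 0
  expect_identical(one@diffusivity, 0)     # concentrated in a single artery
  four <- scorePanel(c(LM = 100, LAD = 100, LCX = 100, RCA = 100))
  expect_equal(four@diffusivity, 0.75)
  expect_error(scorePanel(c(LAD = -1)), "negative")
})

test_that("log-score features are zero exactly when the score is zero", {
  p <- scorePanel(c(LM = 0, LAD = 9, LCX = 99, RCA = 0))
  expect_identical(unname(p@logScores[c("LM", "RCA")]), c(0, 0))
  expect_equal(unname(p@logScores[c("LAD", "LCX")]), c(1, 2))
})
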