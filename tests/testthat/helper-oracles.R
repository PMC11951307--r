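# Independent brute-force Agatston oracle: enumerates candidate voxels per
# slice and merges 8-connected components by repeated pairwise sweeps over a
# randomized voxel order (a different traversal than the engine's flood fill).
bruteForceAgatston <- function(hu, mask, spacing, thresholdHu = 130,
                               minAreaMm2 = 1, shuffleSeed = 99) {
  set.seed(shuffleSeed)
  pixArea <- spacing[1] * spacing[2]
  thick <- spacing[3] / 3
  total <- 0
  for (z in seq_len(dim(hu)[3])) {
    idx <- which(mask[, , z] & hu[, , z] >= thresholdHu, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    idx <- idx[sample.int(nrow(idx)), , drop = FALSE]
    comp <- seq_len(nrow(idx))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(idx))) for (j in seq_len(nrow(idx))) {
        if (comp[i] != comp[j] &&
            max(abs(idx[i, ] - idx[j, ])) <= 1) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      vox <- which(comp == cc)
      area <- length(vox) * pixArea
      if (area < minAreaMm2) next
      peak <- max(hu[, , z][idx[vox, , drop = FALSE]])
      w <- findInterval(peak, c(130, 200, 300, 400))
      total <- total + area * w * thick
    }
  }
  total
}

# Small random lesion phantom for the oracle-equivalence property: a modest
# grid with 1-3 lesions of random position, size and attenuation in one
# territory.
randomLesionPhantom <- function(seed) {
  set.seed(seed)
  nLesions <- sample(1:3, 1)
  lesions <- lapply(seq_len(nLesions), function(i)
    lesionSpec("LAD",
               center = runif(3, 6, 18) * c(1, 1, 1),
               radius = runif(1, 1, 3.5),
               peakHu = runif(1, 120, 900),
               huProfile = sample(c("uniform", "radial-falloff"), 1)))
  spec <- phantomSpec(gridShape = c(24L, 24L, 8L),
                      voxelSpacing = c(runif(1, 0.4, 1), runif(1, 0.4, 1),
                                       runif(1, 1.5, 3)),
                      pericardiumSemiAxes = c(8, 8, 9),
                      eatShellRho = 0.8, seed = seed)
  # lesion centers are in mm; rescale into the grid extent
  ext <- (spec@gridShape - 1) * spec@voxelSpacing
  lesions <- lapply(lesions, function(l)
    lesionSpec(l@artery, pmin(l@center, ext * 0.8), l@radius, l@peakHu,
               l@huProfile))
  spec@lesions <- lesions
  generatePhantom(spec)
}

# One-slice CTVolume with a given HU matrix (slice thickness in mm).
sliceVolume <- function(huMat, inPlane = c(0.5, 0.5), thick = 3) {
  CTVolume(array(huMat, dim = c(dim(huMat), 1)), c(inPlane, thick))
}

fullMask <- function(vol, role = "LAD") {
  RegionMask(array(TRUE, dim = dim(vol@hu)), vol@spacing, role = role)
}
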