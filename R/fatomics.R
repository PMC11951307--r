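#' Default fat-omics histogram bin edges
#'
#' 20-HU-wide bins spanning the adipose window, -190 to -30 HU.
#'
#' @return Numeric vector of bin edges.
#' @export
fatomicsBinEdges <- function() seq(ADIPOSE_WINDOW[1], ADIPOSE_WINDOW[2], by = 20)

# "Pro_{a}_{b}" tag for bin [lo, hi): absolute HU bounds, outer first.
.binTags <- function(edges) {
  lo <- abs(edges[-length(edges)])
  hi <- abs(edges[-1])
  sprintf("Pro_%d_%d", lo, hi)
}

# Mask voxels that touch the complement (6-neighbourhood; outside the grid
# counts as complement). Returns a 1-based index matrix: the region surface.
.complementBoundary <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  nb <- function(o1, o2, o3)
    pad[(2:(d[1] + 1)) + o1, (2:(d[2] + 1)) + o2, (2:(d[3] + 1)) + o3]
  eroded <- nb(-1, 0, 0) & nb(1, 0, 0) & nb(0, -1, 0) & nb(0, 1, 0) &
            nb(0, 0, -1) & nb(0, 0, 1)
  which(mask & !eroded, arr.ind = TRUE)
}

#' Assign EAT voxels to cranio-caudal slabs and distance ribbons
#'
#' Partitions the epicardial adipose tissue into four equally thick slabs of
#' image slices over the slice range the EAT occupies (slab 1 = top), and
#' into `nRibbons` equal-width bands of Euclidean distance (in mm, respecting
#' anisotropic spacing) from the pericardial boundary inward (ribbon 1 =
#' outermost). The boundary is the set of pericardium voxels adjacent to the
#' exterior; each EAT voxel's depth is its distance to the nearest such voxel.
#'
#' @param eat EAT [RegionMask-class]; must be contained in `pericardium`.
#' @param pericardium Pericardium interior [RegionMask-class].
#' @param spacing Voxel spacing in mm; defaults to the mask spacing.
#' @param nRibbons Number of ribbons (default 5, matching the outer-first
#'   SR1..SR5 naming of the spatial features).
#' @return An [EATGeometry-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 2))
#' geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
#' table(geo@slab)
#' @export
assignSlabsRibbons <- function(eat, pericardium, spacing = eat@spacing,
                               nRibbons = 5L) {
  stopifnot(is(eat, "RegionMask"), is(pericardium, "RegionMask"))
  if (!identical(dim(eat@mask), dim(pericardium@mask)))
    stop("EAT and pericardium masks have mismatched shapes")
  if (!sum(eat@mask))
    stop("EAT mask is empty: no geometry to assign")
  if (any(eat@mask & !pericardium@mask))
    stop("EAT mask is not contained in the pericardium interior")
  nRibbons <- as.integer(nRibbons)
  stopifnot(nRibbons >= 1L)

  idx <- which(eat@mask, arr.ind = TRUE)
  colnames(idx) <- NULL

  # slabs: four equal-thickness bands of the occupied slice range
  zIdx <- idx[, 3]
  zRange <- range(zIdx)
  breaks <- seq(zRange[1] - 0.5, zRange[2] + 0.5, length.out = 5L)
  slab <- findInterval(zIdx, breaks, rightmost.closed = TRUE)
  slab <- pmin(pmax(slab, 1L), 4L)

  # ribbons: equal-width distance-to-boundary bands
  boundIdx <- .complementBoundary(pericardium@mask)
  eatMm <- .worldCoords(idx, spacing)
  boundMm <- .worldCoords(boundIdx, spacing)
  d <- .minDistToSet(eatMm, boundMm)
  dMax <- max(d)
  ribbon <- if (dMax == 0) rep(1L, length(d)) else {
    width <- dMax / nRibbons
    pmin(as.integer(floor(d / width)) + 1L, nRibbons)
  }

  new("EATGeometry", eatMask = eat, pericardiumMask = pericardium,
      voxelIndex = idx, slab = as.integer(slab), ribbon = ribbon,
      boundaryDistance = d, spacing = as.numeric(spacing),
      nRibbons = nRibbons)
}

.regionProbs <- function(hu, edges) {
  inWindow <- hu >= edges[1] & hu < edges[length(edges)]
  n <- sum(inWindow)
  if (n == 0) return(rep(0, length(edges) - 1))
  counts <- graphics::hist(hu[inWindow], breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  counts / n
}

#' Mean and maximum epicardial fat thickness
#'
#' Per-slice radial thickness of the EAT band: from the per-slice centroid of
#' the pericardium, rays are cast at 1-degree steps and sampled finely; the
#' thickness along a ray is the sampled path length through EAT. Returns the
#' mean over all EAT-crossing rays and slices, and the maximum. A
#' single-voxel EAT degenerates to the in-plane voxel extent.
#'
#' @param geometry An [EATGeometry-class].
#' @param spacing Voxel spacing in mm; defaults to the geometry's spacing.
#' @param angleStepDeg Angular step between rays, degrees.
#' @return Named numeric: `mean_mm`, `max_mm`.
#' @export
fatThickness <- function(geometry, spacing = geometry@spacing,
                         angleStepDeg = 1) {
  stopifnot(is(geometry, "EATGeometry"))
  eat <- geometry@eatMask@mask
  peri <- geometry@pericardiumMask@mask
  d <- dim(eat)
  inPlane <- mean(spacing[1:2])
  if (nrow(geometry@voxelIndex) == 1L)
    return(c(mean_mm = inPlane, max_mm = inPlane))

  step <- 0.2 * min(spacing[1:2])
  maxR <- sqrt(sum(((d - 1) * spacing)[1:2]^2))
  rSeq <- seq(0, maxR, by = step)
  angles <- seq(0, 2 * pi, by = angleStepDeg * pi / 180)
  angles <- angles[angles < 2 * pi]

  perRay <- c()
  for (z in sort(unique(geometry@voxelIndex[, 3]))) {
    eatSlice <- eat[, , z]
    periSlice <- peri[, , z]
    if (!any(eatSlice)) next
    ctrIdx <- which(if (any(periSlice)) periSlice else eatSlice,
                    arr.ind = TRUE)
    ctr <- (colMeans(ctrIdx) - 1) * spacing[1:2]
    for (th in angles) {
      xs <- ctr[1] + rSeq * cos(th)
      ys <- ctr[2] + rSeq * sin(th)
      i <- round(xs / spacing[1]) + 1
      j <- round(ys / spacing[2]) + 1
      ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
      if (!any(ok)) next
      hit <- eatSlice[cbind(i[ok], j[ok])]
      nHit <- sum(hit)
      if (nHit > 0) perRay <- c(perRay, nHit * step)
    }
  }
  if (!length(perRay)) return(c(mean_mm = 0, max_mm = 0))
  c(mean_mm = mean(perRay), max_mm = max(perRay))
}

#' Extract the fat-omics feature vector
#'
#' Computes the three fat-omics feature families from a CT volume and an EAT
#' slab/ribbon geometry:
#' \describe{
#'   \item{morphological}{EAT volume (voxel count x voxel volume, mm^3),
#'     principal axis lengths (4 x sqrt of the eigenvalues of the EAT
#'     voxel-coordinate covariance, mm), and mean/max fat thickness (mm).}
#'   \item{intensity}{Minimum, maximum, and mean HU, skewness, and
#'     whole-EAT histogram-bin probabilities over the adipose window.}
#'   \item{spatial}{`SR{k}_Pro_{a}_{b}`: the probability that an EAT voxel in
#'     ribbon k has HU in \[-a, -b), for consecutive 20-HU bins; `SS{k}_...`
#'     analogously per cranio-caudal slab.}
#' }
#' Probabilities are normalized within each nonempty ribbon/slab over the
#' full bin partition, so they sum to 1 there; an empty ribbon's features are
#' emitted as 0 with a warning.
#'
#' @param volume A [CTVolume-class].
#' @param geometry An [EATGeometry-class] aligned to `volume`.
#' @param binEdges Strictly increasing HU bin edges covering the adipose
#'   window; default [fatomicsBinEdges()].
#' @return A named numeric feature vector with a stable name schema.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 2))
#' geo <- assignSlabsRibbons(ph$eat, ph$pericardium)
#' fv <- extractFeatures(ph$volume, geo)
#' fv["eat_volume_mm3"]
#' @export
extractFeatures <- function(volume, geometry, binEdges = fatomicsBinEdges()) {
  stopifnot(is(volume, "CTVolume"), is(geometry, "EATGeometry"))
  if (!identical(dim(volume@hu), dim(geometry@eatMask@mask)))
    stop("geometry is not aligned to the volume (shape mismatch)")
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("binEdges must be strictly increasing")

  sp <- geometry@spacing
  idx <- geometry@voxelIndex
  hu <- volume@hu[idx]
  n <- nrow(idx)
  tags <- .binTags(binEdges)

  out <- c(eat_volume_mm3 = n * prod(sp))
  coords <- .worldCoords(idx, sp)
  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  out <- c(out, stats::setNames(4 * sqrt(ev),
                                paste0("principal_axis_", 1:3, "_mm")))
  th <- fatThickness(geometry, sp)
  out <- c(out, eat_thickness_mean_mm = unname(th["mean_mm"]),
           eat_thickness_max_mm = unname(th["max_mm"]))

  m <- mean(hu)
  s <- stats::sd(hu)
  skew <- if (n > 2 && s > 0) mean((hu - m)^3) / (mean((hu - m)^2))^1.5 else 0
  out <- c(out, eat_min_hu = min(hu), eat_max_hu = max(hu), eat_mean_hu = m,
           eat_skewness = skew,
           stats::setNames(.regionProbs(hu, binEdges), tags))

  for (k in seq_len(geometry@nRibbons)) {
    sel <- geometry@ribbon == k
    if (!any(sel)) {
      warning(sprintf("ribbon %d is empty; its probability features are 0", k))
      probs <- rep(0, length(tags))
    } else probs <- .regionProbs(hu[sel], binEdges)
    out <- c(out, stats::setNames(probs, sprintf("SR%d_%s", k, tags)))
  }
  for (k in 1:4) {
    sel <- geometry@slab == k
    if (!any(sel)) {
      warning(sprintf("slab %d is empty; its probability features are 0", k))
      probs <- rep(0, length(tags))
    } else probs <- .regionProbs(hu[sel], binEdges)
    out <- c(out, stats::setNames(probs, sprintf("SS%d_%s", k, tags)))
  }
  out
}
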