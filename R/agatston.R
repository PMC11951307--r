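#' Agatston density weight for a peak attenuation
#'
#' Weight 1 for peak HU 130-199, 2 for 200-299, 3 for 300-399, 4 for >= 400.
#'
#' @param peakHu Peak lesion attenuation (HU), >= 130.
#' @return Integer weight in 1..4.
#' @export
agatstonWeight <- function(peakHu) {
  stopifnot(all(peakHu >= 130))
  findInterval(peakHu, c(130, 200, 300, 400))
}

#' Detect calcified lesions in an artery territory
#'
#' Standard Agatston lesion detection: on each axial slice, connected
#' components (8-connectivity by default) of territory voxels at or above the
#' attenuation threshold; components below the minimum area are discarded.
#' Each surviving component contributes `area x weight x slice_thickness / 3`
#' Agatston units, the thickness factor normalizing non-3-mm acquisitions.
#'
#' @param volume A [CTVolume-class].
#' @param territory A [RegionMask-class] for the artery's calcium territory,
#'   aligned to `volume`.
#' @param thresholdHu Attenuation threshold in HU.
#' @param minAreaMm2 Minimum lesion area in mm^2.
#' @param connectivity In-plane connectivity, 8 or 4.
#' @return A data frame with one row per lesion: `artery`, `slice`,
#'   `voxel_count`, `area_mm2`, `peak_hu`, `weight`, `score`.
#' @examples
#' ph <- generatePhantom(phantomSpec(
#'   lesions = list(lesionSpec("LAD", center = c(23, 23, 21),
#'                             radius = 3, peakHu = 450)),
#'   seed = 1))
#' findLesions(ph$volume, ph$territories$LAD)
#' @export
findLesions <- function(volume, territory, thresholdHu = 130,
                        minAreaMm2 = 1, connectivity = 8) {
  stopifnot(is(volume, "CTVolume"), is(territory, "RegionMask"))
  if (!identical(dim(volume@hu), dim(territory@mask)))
    stop("territory mask is not aligned to the volume (shape mismatch)")
  stopifnot(connectivity %in% c(4, 8))
  sp <- volume@spacing
  pixArea <- sp[1] * sp[2]
  thickFactor <- sp[3] / 3
  nSlices <- dim(volume@hu)[3]
  rows <- list()
  for (z in seq_len(nSlices)) {
    m <- territory@mask[, , z] & volume@hu[, , z] >= thresholdHu
    if (!any(m)) next
    lab <- .labelComponents2D(m, as.integer(connectivity))
    huSlice <- volume@hu[, , z]
    for (comp in seq_len(max(lab))) {
      vox <- which(lab == comp)
      area <- length(vox) * pixArea
      if (area < minAreaMm2) next
      peak <- max(huSlice[vox])
      w <- agatstonWeight(peak)
      rows[[length(rows) + 1L]] <- data.frame(
        artery = territory@role, slice = z, voxel_count = length(vox),
        area_mm2 = area, peak_hu = peak, weight = w,
        score = area * w * thickFactor)
    }
  }
  if (!length(rows))
    return(data.frame(artery = character(), slice = integer(),
                      voxel_count = integer(), area_mm2 = numeric(),
                      peak_hu = numeric(), weight = integer(),
                      score = numeric()))
  do.call(rbind, rows)
}

.buildPanel <- function(scores) {
  full <- stats::setNames(numeric(length(ARTERIES)), ARTERIES)
  full[names(scores)] <- scores
  if (any(full < 0)) stop("negative per-artery Agatston score")
  total <- sum(full)
  diffus <- if (total > 0) 1 - max(full) / total else 0
  new("ScorePanel", scores = full, total = total,
      logScores = log10(full + 1), logTotal = log10(total + 1),
      diffusivity = diffus, highCac = total > 1000)
}

#' Assemble the Agatston feature panel
#'
#' Builds a [ScorePanel-class] from per-artery lesions (as returned by
#' [findLesions()]) or directly from named per-artery scores. Arteries not
#' present are scored 0. The panel carries the per-artery and total scores,
#' log10(score + 1) transforms, the diffusivity index
#' (1 - most-affected-vessel score / total; 0 when the total is 0), and the
#' high-CAC flag (total strictly greater than 1000).
#'
#' @param x Either a named list of lesion data frames keyed by artery, or a
#'   named numeric vector of per-artery Agatston scores.
#' @return A [ScorePanel-class].
#' @examples
#' scorePanel(c(LM = 43, LAD = 1168, LCX = 633, RCA = 1183))
#' @export
setGeneric("scorePanel", function(x) standardGeneric("scorePanel"))

#' @rdname scorePanel
#' @export
setMethod("scorePanel", "numeric", function(x) {
  if (is.null(names(x)) || !all(names(x) %in% ARTERIES))
    stop("per-artery scores must be named with LM, LAD, LCX, RCA")
  .buildPanel(x)
})

#' @rdname scorePanel
#' @export
setMethod("scorePanel", "list", function(x) {
  if (length(x) && (is.null(names(x)) || !all(names(x) %in% ARTERIES)))
    stop("lesion lists must be keyed by artery (LM, LAD, LCX, RCA)")
  scores <- vapply(x, function(df) {
    if (nrow(df) && any(df$score < 0)) stop("negative lesion score")
    sum(df$score)
  }, numeric(1))
  .buildPanel(scores)
})

#' Score a volume against a set of artery territories
#'
#' Convenience wrapper: runs [findLesions()] for each territory and
#' assembles the [ScorePanel-class].
#'
#' @param volume A [CTVolume-class].
#' @param territories Named list of [RegionMask-class] keyed by artery.
#' @param ... Passed to [findLesions()].
#' @return A [ScorePanel-class].
#' @export
scoreVolume <- function(volume, territories, ...) {
  lesions <- lapply(territories, function(t) findLesions(volume, t, ...))
  names(lesions) <- names(territories)
  scorePanel(lesions)
}

#' Flatten a ScorePanel to a one-row data frame
#'
#' Column names match the Agatston feature block of the cohort tables:
#' `lm_score` .. `rca_score`, `total_score`, the log10(x + 1) transforms,
#' `diffusivity_index`, and `high_cac`.
#'
#' @param x A [ScorePanel-class].
#' @param row.names,optional,... Ignored (S3 signature compatibility).
#' @return A one-row data frame.
#' @export
as.data.frame.ScorePanel <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- as.list(stats::setNames(x@scores, paste0(tolower(ARTERIES), "_score")))
  out <- c(out, stats::setNames(as.list(x@logScores),
                                paste0("log_", tolower(ARTERIES), "_score")))
  out$total_score <- x@total
  out$log_total_score <- x@logTotal
  out$diffusivity_index <- x@diffusivity
  out$high_cac <- as.numeric(x@highCac)
  as.data.frame(out)
}
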