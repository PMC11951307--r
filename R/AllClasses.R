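#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib ctcsPR, .registration = TRUE
NULL

ARTERIES <- c("LM", "LAD", "LCX", "RCA")
PR_ARTERIES <- c("LAD", "LCX", "RCA")
ARTERY_REGIONS <- c("proximal", "mid", "distal")
FEATURE_CLASSES <- c("clinical", "agatston", "fatomics")

#' CT volume in Hounsfield units
#'
#' A 3-D grid of Hounsfield units with anisotropic voxel spacing. The third
#' array axis is the cranio-caudal (slice) axis by convention; [readVolume()]
#' canonicalizes permuted inputs to this layout. Voxel indices are mapped to
#' world coordinates as `(index - 1) * spacing` mm (voxel centres).
#'
#' @slot hu 3-D numeric array of Hounsfield units.
#' @slot spacing Numeric length-3 voxel spacing in mm
#'   (in-plane x, in-plane y, slice thickness).
#'
#' @export
setClass("CTVolume", representation(hu = "array", spacing = "numeric"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@hu)) != 3L)
    msg <- c(msg, "hu must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (any(!is.finite(object@hu)))
    msg <- c(msg, "all HU values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param hu 3-D numeric array of Hounsfield units (third axis cranio-caudal).
#' @param spacing Voxel spacing in mm: in-plane x, in-plane y, slice thickness.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(0, c(4, 4, 2)), spacing = c(0.5, 0.5, 3))
#' @export
CTVolume <- function(hu, spacing) {
  new("CTVolume", hu = hu, spacing = as.numeric(spacing))
}

#' Boolean region mask aligned to a CT volume
#'
#' @slot mask 3-D logical array, same dimensions as the volume it annotates.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot role Character label: e.g. "pericardium", "eat", or an artery
#'   territory ("LM", "LAD", "LCX", "RCA").
#'
#' @export
setClass("RegionMask",
         representation(mask = "array", spacing = "numeric", role = "character"))

setValidity("RegionMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3-D logical array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
  if (length(object@role) != 1L)
    msg <- c(msg, "role must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionMask
#'
#' @param mask 3-D logical array.
#' @param spacing Voxel spacing in mm.
#' @param role Region role label.
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(mask, spacing, role = "region") {
  storage.mode(mask) <- "logical"
  new("RegionMask", mask = mask, spacing = as.numeric(spacing), role = role)
}

#' Agatston-score feature panel
#'
#' Per-patient Agatston-derived features: per-artery and total scores, base-10
#' logarithms of score + 1, the diffusivity index, and the high-CAC flag.
#' The diffusivity index is 1 minus the ratio of the most affected vessel's
#' score to the total score (0 when the total is 0); high CAC means a total
#' score strictly greater than 1000.
#'
#' @slot scores Named numeric: Agatston score per artery (LM, LAD, LCX, RCA).
#' @slot total Total Agatston score.
#' @slot logScores Named numeric: log10(score + 1) per artery.
#' @slot logTotal log10(total + 1).
#' @slot diffusivity Diffusivity index in [0, 1).
#' @slot highCac Logical: total score strictly exceeds 1000.
#'
#' @export
setClass("ScorePanel",
         representation(scores = "numeric", total = "numeric",
                        logScores = "numeric", logTotal = "numeric",
                        diffusivity = "numeric", highCac = "logical"))

setValidity("ScorePanel", function(object) {
  msg <- character()
  if (!identical(names(object@scores), ARTERIES))
    msg <- c(msg, "scores must be named LM, LAD, LCX, RCA")
  if (any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
  if (abs(object@total - sum(object@scores)) > 1e-8)
    msg <- c(msg, "total must equal the sum of per-artery scores")
  if (object@diffusivity < 0 || object@diffusivity >= 1)
    msg <- c(msg, "diffusivity index must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Slab/ribbon geometry of the epicardial fat
#'
#' Assigns every epicardial adipose tissue (EAT) voxel to one of four equally
#' thick cranio-caudal slabs (over the slice range the EAT occupies) and one
#' of `nRibbons` equal-width distance bands ("ribbons") measured from the
#' pericardial boundary inward; ribbon 1 is the outermost band.
#'
#' @slot eatMask The EAT [RegionMask-class].
#' @slot pericardiumMask The pericardium interior [RegionMask-class].
#' @slot voxelIndex Integer matrix (n x 3) of 1-based EAT voxel indices.
#' @slot slab Integer vector (1-4) per EAT voxel.
#' @slot ribbon Integer vector (1..nRibbons) per EAT voxel.
#' @slot boundaryDistance Numeric vector: mm distance of each EAT voxel from
#'   the pericardial boundary.
#' @slot spacing Voxel spacing in mm.
#' @slot nRibbons Number of ribbons.
#'
#' @export
setClass("EATGeometry",
         representation(eatMask = "RegionMask", pericardiumMask = "RegionMask",
                        voxelIndex = "matrix", slab = "integer",
                        ribbon = "integer", boundaryDistance = "numeric",
                        spacing = "numeric", nRibbons = "integer"))

setValidity("EATGeometry", function(object) {
  n <- nrow(object@voxelIndex)
  msg <- character()
  if (n == 0L) msg <- c(msg, "geometry must contain at least one EAT voxel")
  if (length(object@slab) != n || length(object@ribbon) != n)
    msg <- c(msg, "slab and ribbon assignments must cover every EAT voxel")
  if (length(object@slab) && (any(object@slab < 1L) || any(object@slab > 4L)))
    msg <- c(msg, "slab indices must lie in 1..4")
  if (length(object@ribbon) &&
      (any(object@ribbon < 1L) || any(object@ribbon > object@nRibbons)))
    msg <- c(msg, "ribbon indices must lie in 1..nRibbons")
  if (length(msg)) msg else TRUE
})

#' Vessel outer-diameter profile for remodeling assessment
#'
#' Ordered outer-diameter samples along a coronary segment, with index
#' intervals marking the plaque and the reference segments directly proximal
#' and distal to it.
#'
#' @slot artery Artery name ("LM", "LAD", "LCX", "RCA").
#' @slot region Segment region: "proximal", "mid", or "distal".
#' @slot diameters Ordered outer-diameter samples in mm, all > 0.
#' @slot plaqueSpan Integer indices of the plaque interval.
#' @slot proximalRef Integer indices of the proximal reference interval.
#' @slot distalRef Integer indices of the distal reference interval.
#'
#' @export
setClass("DiameterProfile",
         representation(artery = "character", region = "character",
                        diameters = "numeric", plaqueSpan = "integer",
                        proximalRef = "integer", distalRef = "integer"))

setValidity("DiameterProfile", function(object) {
  msg <- character()
  n <- length(object@diameters)
  if (!object@artery %in% ARTERIES) msg <- c(msg, "unknown artery")
  if (!object@region %in% ARTERY_REGIONS) msg <- c(msg, "unknown region")
  if (n == 0L || any(!is.finite(object@diameters)) || any(object@diameters <= 0))
    msg <- c(msg, "diameters must be finite and strictly positive")
  for (nm in c("plaqueSpan", "proximalRef", "distalRef")) {
    idx <- slot(object, nm)
    if (length(idx) == 0L || any(idx < 1L) || any(idx > n))
      msg <- c(msg, sprintf("%s must be a non-empty index interval within the profile", nm))
  }
  if (length(intersect(object@plaqueSpan, object@proximalRef)) ||
      length(intersect(object@plaqueSpan, object@distalRef)))
    msg <- c(msg, "reference intervals must be disjoint from the plaque span")
  if (length(msg)) msg else TRUE
})

#' Elastic-net feature-selection result
#'
#' @slot selected Data frame of retained features ordered by importance
#'   (absolute standardized coefficient), with columns `feature`,
#'   `coefficient`, `importance`, `ci_low`, `ci_high`.
#' @slot alpha Elastic-net mixing parameter.
#' @slot lambdaPath The regularization path (decreasing).
#' @slot lambdaOpt The cross-validation-optimal penalty.
#' @slot nzeroPath Number of nonzero coefficients at each path value; the
#'   path starts at the penalty that zeroes every coefficient.
#'
#' @export
setClass("SelectionResult",
         representation(selected = "data.frame", alpha = "numeric",
                        lambdaPath = "numeric", lambdaOpt = "numeric",
                        nzeroPath = "integer"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (is.unsorted(rev(object@lambdaPath)))
    msg <- c(msg, "lambdaPath must be decreasing")
  if (length(msg)) msg else TRUE
})

#' Repeated cross-validation evaluation
#'
#' @slot perRepetition Data frame with one row per repetition: `repetition`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc` (proportions in [0, 1]).
#' @slot oofScores Numeric matrix (patients x repetitions) of out-of-fold
#'   predicted probabilities.
#' @slot labels Logical vector of true PR labels.
#' @slot nRepetitions Number of repetitions.
#' @slot nFolds Number of folds per repetition.
#' @slot model Model number (1-3) evaluated.
#' @slot backend Classifier backend used.
#'
#' @export
setClass("CVEvaluation",
         representation(perRepetition = "data.frame", oofScores = "matrix",
                        labels = "logical", nRepetitions = "integer",
                        nFolds = "integer", model = "integer",
                        backend = "character"))

setValidity("CVEvaluation", function(object) {
  msg <- character()
  metr <- unlist(object@perRepetition[c("sensitivity", "specificity",
                                        "accuracy", "auc")])
  if (any(metr < -1e-9 | metr > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "metrics must lie in [0, 1]")
  if (nrow(object@perRepetition) != object@nRepetitions)
    msg <- c(msg, "perRepetition must have one row per repetition")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@hu)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x "),
              min(object@hu), max(object@hu)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RegionMask '%s': %d x %d x %d voxels, %d set (%.1f%%)\n",
              object@role, d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "ScorePanel", function(object) {
  cat("Agatston score panel\n")
  cat("  per-artery:",
      paste(sprintf("%s %.1f", names(object@scores), object@scores),
            collapse = ", "), "\n")
  cat(sprintf("  total %.1f | log10(total+1) %.3f | diffusivity %.3f | high CAC %s\n",
              object@total, object@logTotal, object@diffusivity,
              object@highCac))
})

setMethod("show", "EATGeometry", function(object) {
  cat(sprintf("EATGeometry: %d EAT voxels, 4 slabs, %d ribbons (1 = outermost)\n",
              nrow(object@voxelIndex), object@nRibbons))
  cat("  voxels per ribbon:",
      paste(tabulate(object@ribbon, object@nRibbons), collapse = ", "), "\n")
})

setMethod("show", "DiameterProfile", function(object) {
  cat(sprintf("DiameterProfile %s/%s: %d samples, plaque [%d..%d]\n",
              object@artery, object@region, length(object@diameters),
              min(object@plaqueSpan), max(object@plaqueSpan)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d features at lambda = %.4g (alpha = %g)\n",
              nrow(object@selected), object@lambdaOpt, object@alpha))
  if (nrow(object@selected))
    print(utils::head(object@selected, 10), row.names = FALSE)
})

setMethod("show", "CVEvaluation", function(object) {
  s <- summary(object)
  cat(sprintf("CVEvaluation: Model %d, backend '%s', %d x %d-fold CV\n",
              object@model, object@backend, object@nRepetitions, object@nFolds))
  cat(sprintf("  sensitivity %.1f +/- %.1f%%  specificity %.1f +/- %.1f%%\n",
              s["sensitivity", "mean"], s["sensitivity", "sd"],
              s["specificity", "mean"], s["specificity", "sd"]))
  cat(sprintf("  accuracy    %.1f +/- %.1f%%  AUC         %.1f +/- %.1f%%\n",
              s["accuracy", "mean"], s["accuracy", "sd"],
              s["auc", "mean"], s["auc", "sd"]))
})
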