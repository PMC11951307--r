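#' Read a CT volume or mask from NIfTI
#'
#' Reads a NIfTI file into a [CTVolume-class] (or [RegionMask-class] with
#' `asMask = TRUE`), canonicalizing the axis order so the declared
#' cranio-caudal axis becomes the third array axis and permuting the voxel
#' spacing consistently. Volumes with missing or non-positive spacing
#' metadata are rejected; spacing is never silently assumed.
#'
#' @param path Path to a NIfTI file.
#' @param sliceAxis Which stored axis (1-3) is cranio-caudal.
#' @param asMask Read as a boolean [RegionMask-class].
#' @param role Role label when `asMask = TRUE`.
#' @return A [CTVolume-class] or [RegionMask-class].
#' @export
readVolume <- function(path, sliceAxis = 3L, asMask = FALSE, role = "region") {
  stopifnot(file.exists(path), sliceAxis %in% 1:3)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("'%s' lacks usable voxel-spacing metadata; refusing to assume 1 mm",
                 path))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # strip image class/attributes
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume")
  if (sliceAxis != 3L) {
    perm <- c(setdiff(1:3, sliceAxis), sliceAxis)
    arr <- aperm(arr, perm)
    spacing <- spacing[perm]
  }
  if (asMask) RegionMask(arr != 0, spacing, role = role)
  else CTVolume(arr, spacing)
}

#' Write a CT volume or mask to NIfTI
#'
#' HU grids are stored as 64-bit floats so a write/read round-trip is
#' bit-exact; masks as 8-bit integers.
#'
#' @param x A [CTVolume-class] or [RegionMask-class].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "CTVolume")) {
    arr <- x@hu
    dt <- "double"
    spacing <- x@spacing
  } else if (is(x, "RegionMask")) {
    arr <- array(as.integer(x@mask), dim = dim(x@mask))
    dt <- "uint8"
    spacing <- x@spacing
  } else stop("x must be a CTVolume or RegionMask")
  attr(arr, "pixdim") <- spacing
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write a cohort or feature table to CSV
#'
#' @param x A data frame (e.g. from [generateCohort()]).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path with one row per patient (see [generateCohort()] for
#'   the column dictionary).
#' @return A data frame.
#' @export
readCohort <- function(path) {
  stopifnot(file.exists(path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a FeatureTable to CSV
#'
#' Two files: `<stem>.csv` (patients x features plus `patient_id`, `pr`, and
#' any survival columns) and `<stem>_features.csv` (the feature/class
#' dictionary).
#'
#' @param x A [FeatureTable-class].
#' @param stem Path stem (without extension).
#' @return The data CSV path, invisibly.
#' @export
writeFeatureTable <- function(x, stem) {
  stopifnot(is(x, "FeatureTable"))
  df <- as.data.frame(designMatrix(x, rownames(x)))
  cd <- SummarizedExperiment::colData(x)
  df <- cbind(data.frame(patient_id = colnames(x), pr = cd$pr), df)
  if ("time_years" %in% names(cd)) df$time_years <- cd$time_years
  if ("event" %in% names(cd)) df$event <- cd$event
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = rownames(x),
                              class = unname(featureClass(x))),
                   paste0(stem, "_features.csv"), row.names = FALSE)
  invisible(paste0(stem, ".csv"))
}

#' Read a FeatureTable from CSV
#'
#' Inverse of [writeFeatureTable()]. The dictionary's classes are validated:
#' an unknown feature tag is a schema error naming the column.
#'
#' @param stem Path stem used by [writeFeatureTable()].
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  dict <- utils::read.csv(paste0(stem, "_features.csv"),
                          stringsAsFactors = FALSE)
  bad <- !dict$class %in% FEATURE_CLASSES
  if (any(bad))
    stop(sprintf("unknown feature tag '%s' for column '%s'",
                 dict$class[bad][1], dict$feature[bad][1]))
  mat <- t(as.matrix(df[dict$feature]))
  colnames(mat) <- df$patient_id
  FeatureTable(mat, dict$class, df$pr,
               time = if ("time_years" %in% names(df)) df$time_years,
               event = if ("event" %in% names(df)) df$event)
}
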