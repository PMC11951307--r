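#' Patient-by-feature table with feature-class tags
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' the feature matrix (features in rows, patients in columns), whose
#' `rowData` tags every feature as `clinical`, `agatston`, or `fatomics`,
#' and whose `colData` carries the PR label (and, when available, the MACE
#' follow-up time and event indicator). The tags define the nested model
#' groupings: Model 1 = clinical, Model 2 = clinical + agatston,
#' Model 3 = all three classes.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"featureClass" %in% names(rd))
    msg <- c(msg, "rowData must carry a featureClass column")
  else if (!all(rd$featureClass %in% FEATURE_CLASSES))
    msg <- c(msg, "featureClass values must be clinical, agatston, or fatomics")
  if (!"pr" %in% names(cd) || !is.logical(cd$pr))
    msg <- c(msg, "colData must carry a logical pr label")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature names are not allowed")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureTable-class
#' @param features Numeric matrix, features x patients, with feature row
#'   names.
#' @param featureClass Character vector tagging each feature row.
#' @param pr Logical PR label per patient.
#' @param time,event Optional MACE follow-up time (years) and event
#'   indicator per patient.
#' @return A `FeatureTable`.
#' @export
FeatureTable <- function(features, featureClass, pr, time = NULL,
                         event = NULL) {
  cd <- S4Vectors::DataFrame(pr = as.logical(pr))
  if (!is.null(time)) cd$time_years <- as.numeric(time)
  if (!is.null(event)) cd$event <- as.numeric(event)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features),
    rowData = S4Vectors::DataFrame(featureClass = featureClass),
    colData = cd)
  new("FeatureTable", se)
}

#' Assemble a FeatureTable from a simulated cohort
#'
#' Tags the cohort's columns by feature class: the clinical covariates
#' (including the derived BMI/age bands), the Agatston-derived block, and
#' the fat-omics block.
#'
#' @param cohort A data frame from [generateCohort()].
#' @return A [FeatureTable-class].
#' @examples
#' ft <- buildFeatureTable(generateCohort(cohortSpec(nPatients = 100)))
#' table(featureClass(ft))
#' @export
buildFeatureTable <- function(cohort) {
  stopifnot(is.data.frame(cohort), "pr" %in% names(cohort))
  agCols <- c(paste0(tolower(ARTERIES), "_score"),
              paste0("log_", tolower(ARTERIES), "_score"),
              "total_score", "log_total_score", "diffusivity_index",
              "high_cac")
  meta <- c("patient_id", "pr", "time_years", "event")
  featCols <- setdiff(names(cohort), meta)
  fatCols <- featCols[grepl("^(SR|SS)[0-9]+_Pro_|^eat_", featCols)]
  clinCols <- setdiff(featCols, c(agCols, fatCols))
  ordered <- c(clinCols, intersect(agCols, featCols), fatCols)
  mat <- t(as.matrix(cohort[ordered]))
  colnames(mat) <- cohort$patient_id
  cls <- c(rep("clinical", length(clinCols)),
           rep("agatston", length(intersect(agCols, featCols))),
           rep("fatomics", length(fatCols)))
  FeatureTable(mat, cls, cohort$pr,
               time = if ("time_years" %in% names(cohort)) cohort$time_years,
               event = if ("event" %in% names(cohort)) cohort$event)
}

#' Feature-class tags of a FeatureTable
#' @param x A [FeatureTable-class].
#' @return Named character vector of tags (`clinical`, `agatston`,
#'   `fatomics`), one per feature.
#' @export
featureClass <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  stats::setNames(SummarizedExperiment::rowData(x)$featureClass, rownames(x))
}

#' PR labels of a FeatureTable
#' @param x A [FeatureTable-class].
#' @return Logical vector, one per patient.
#' @export
prLabels <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  SummarizedExperiment::colData(x)$pr
}

#' Feature names entering a given model
#'
#' Model 1 uses the clinical features, Model 2 adds the Agatston-derived
#' features, Model 3 adds the fat-omics features.
#'
#' @param x A [FeatureTable-class].
#' @param model Integer 1, 2, or 3.
#' @return Character vector of feature names.
#' @export
modelFeatures <- function(x, model = 3) {
  stopifnot(model %in% 1:3)
  classes <- FEATURE_CLASSES[seq_len(model)]
  names(featureClass(x))[featureClass(x) %in% classes]
}

#' Patients-by-features design matrix for a model
#'
#' @param x A [FeatureTable-class].
#' @param features Feature names; defaults to [modelFeatures()] of `model`.
#' @param model Model number used when `features` is NULL.
#' @return Numeric matrix, patients in rows.
#' @export
designMatrix <- function(x, features = NULL, model = 3) {
  if (is.null(features)) features <- modelFeatures(x, model)
  miss <- setdiff(features, rownames(x))
  if (length(miss))
    stop(sprintf("unknown features: %s", paste(miss, collapse = ", ")))
  t(SummarizedExperiment::assay(x, "features")[features, , drop = FALSE])
}

setMethod("show", "FeatureTable", function(object) {
  tags <- table(featureClass(object))
  cat(sprintf("FeatureTable: %d features x %d patients (%s); PR prevalence %.1f%%\n",
              nrow(object), ncol(object),
              paste(sprintf("%s %d", names(tags), tags), collapse = ", "),
              100 * mean(prLabels(object))))
})
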