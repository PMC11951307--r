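#' Synthetic cohort specification
#'
#' Parameters of the tabular cohort simulator. Defaults are calibrated to the
#' published arm-wise moments of a CT calcium-scoring cohort with positive
#' remodeling (PR) prevalence 32.4%: clinical covariates are drawn from
#' arm-specific normal/Bernoulli models, per-vessel Agatston scores from
#' arm-specific log10-scale normals clamped at zero (the zero clamp yields the
#' point mass of calcium-free patients), and a small fat-omics block from
#' synthetic arm-specific normals. Covariates are drawn independently given
#' the PR label (correlations are not published); the BMI >= 30 and
#' age 60-75 band indicators are derived from the continuous draws.
#'
#' Event times follow an exponential baseline hazard, multiplied by
#' `exp(logHr)` for PR-positive patients; censoring is administrative at
#' `followupYears` plus an independent uniform early-censoring mechanism.
#'
#' @slot nPatients Cohort size.
#' @slot prPrevalence Bernoulli probability of the PR label.
#' @slot clinical Data frame: per-covariate family and arm parameters
#'   (columns `feature`, `type`, `pr_param1`, `pr_param2`, `non_param1`,
#'   `non_param2`, `clamp_min`). For `type = "continuous"` the parameters are
#'   mean and SD; for `"binary"` param1 is the event proportion.
#' @slot agatston Data frame: per-vessel log10(score + 1) mean and SD by arm.
#' @slot fatomics Data frame: per-feature arm means and SDs (synthetic
#'   calibration; the source cohort publishes no fat-omics moments).
#' @slot baselineHazard Baseline event rate (per person-year).
#' @slot logHr Log hazard ratio for actual PR.
#' @slot censorRate Probability of early (uniform) censoring.
#' @slot followupYears Administrative follow-up window (years).
#' @slot missingRate Missing-completely-at-random rate applied to clinical
#'   covariates (0 disables).
#' @slot seed Integer RNG seed.
#'
#' @export
setClass("CohortSpec",
         representation(nPatients = "integer", prPrevalence = "numeric",
                        clinical = "data.frame", agatston = "data.frame",
                        fatomics = "data.frame", baselineHazard = "numeric",
                        logHr = "numeric", censorRate = "numeric",
                        followupYears = "numeric", missingRate = "numeric",
                        seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be positive")
  if (object@prPrevalence <= 0 || object@prPrevalence >= 1)
    msg <- c(msg, "prPrevalence must lie strictly between 0 and 1")
  cl <- object@clinical
  need <- c("feature", "type", "pr_param1", "pr_param2", "non_param1", "non_param2")
  if (!all(need %in% names(cl)))
    msg <- c(msg, "clinical model needs columns feature/type/arm parameters")
  else {
    cont <- cl$type == "continuous"
    if (any(c(cl$pr_param2[cont], cl$non_param2[cont]) < 0, na.rm = TRUE))
      msg <- c(msg, "continuous covariate SDs must be non-negative")
    bin <- cl$type == "binary"
    p <- c(cl$pr_param1[bin], cl$non_param1[bin])
    if (any(p < 0 | p > 1, na.rm = TRUE))
      msg <- c(msg, "binary covariate proportions must lie in [0, 1]")
  }
  if (any(c(object@agatston$pr_sd, object@agatston$non_sd) < 0))
    msg <- c(msg, "agatston log-scale SDs must be non-negative")
  if (object@baselineHazard <= 0)
    msg <- c(msg, "baselineHazard must be positive")
  if (object@censorRate < 0 || object@censorRate > 1)
    msg <- c(msg, "censorRate must lie in [0, 1]")
  if (object@followupYears <= 0)
    msg <- c(msg, "followupYears must be positive")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

.calibration <- function(which) {
  path <- system.file("extdata",
                      sprintf("cohort_calibration_%s.csv", which),
                      package = "ctcsPR", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname CohortSpec-class
#' @param nPatients,prPrevalence,clinical,agatston,fatomics,baselineHazard,logHr,censorRate,followupYears,missingRate,seed
#'   See slot descriptions. The calibration tables default to the files
#'   shipped under `inst/extdata/`.
#' @return A `CohortSpec`.
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 500, seed = 1))
#' mean(cohort$pr)
#' @export
cohortSpec <- function(nPatients = 1324L, prPrevalence = 0.324,
                       clinical = .calibration("clinical"),
                       agatston = .calibration("agatston"),
                       fatomics = .calibration("fatomics_synthetic"),
                       baselineHazard = 0.02, logHr = log(6.5),
                       censorRate = 0.1, followupYears = 5,
                       missingRate = 0, seed = 1L) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      prPrevalence = prPrevalence, clinical = clinical,
      agatston = agatston, fatomics = fatomics,
      baselineHazard = baselineHazard, logHr = logHr,
      censorRate = censorRate, followupYears = followupYears,
      missingRate = missingRate, seed = as.integer(seed))
}

#' Planted-signal cohort specification
#'
#' A variant of [cohortSpec()] in which the clinical covariates carry no
#' signal (both arms share the pooled parameters) while the Agatston and
#' fat-omics blocks keep moderate arm separation (per-vessel log-score shift
#' 0.8 of the pooled SD; fat-omics shifts as calibrated). Used to test that
#' classification performance is driven by the imaging feature blocks:
#' clinical-only models should sit near chance while models that add the
#' imaging blocks should not.
#'
#' @param nPatients,seed,... Passed to [cohortSpec()].
#' @return A [CohortSpec-class].
#' @export
plantedCohortSpec <- function(nPatients = 600L, seed = 1L, ...) {
  cl <- .calibration("clinical")
  # null out clinical signal: both arms get the PR- arm parameters
  cl$pr_param1 <- cl$non_param1
  cl$pr_param2 <- cl$non_param2
  ag <- .calibration("agatston")
  pooled_sd <- (ag$pr_sd + ag$non_sd) / 2
  ag$pr_mean <- ag$non_mean + 0.8 * pooled_sd
  ag$pr_sd <- pooled_sd
  ag$non_sd <- pooled_sd
  cohortSpec(nPatients = nPatients, clinical = cl, agatston = ag,
             seed = seed, ...)
}

.drawArm <- function(n, type, p1, p2, clampMin) {
  if (type == "binary") {
    as.numeric(stats::runif(n) < p1)
  } else {
    x <- stats::rnorm(n, p1, p2)
    if (!is.na(clampMin)) x <- pmax(x, clampMin)
    x
  }
}

#' Generate a synthetic cohort
#'
#' Draws PR labels, arm-conditional clinical covariates, Agatston-derived
#' features, fat-omics features, and censored event times from a
#' [CohortSpec-class]. Reproducible: the spec's seed fully determines the
#' output.
#'
#' @param spec A [CohortSpec-class].
#' @return A data frame with one row per patient: `patient_id`, `pr`
#'   (logical), the clinical covariates (including the derived `bmi_ge30`
#'   and `age_60_75` bands), per-vessel and total Agatston scores with their
#'   log10(x + 1) transforms, `diffusivity_index`, `high_cac`, the fat-omics
#'   block, and `time_years`/`event` for the MACE analysis.
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 200, seed = 3))
#' table(cohort$pr)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nPatients
  pr <- stats::runif(n) < spec@prPrevalence

  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)), pr = pr)

  cl <- spec@clinical
  clampMin <- if ("clamp_min" %in% names(cl)) cl$clamp_min else rep(NA, nrow(cl))
  for (i in seq_len(nrow(cl))) {
    x <- numeric(n)
    x[pr] <- .drawArm(sum(pr), cl$type[i], cl$pr_param1[i], cl$pr_param2[i],
                      clampMin[i])
    x[!pr] <- .drawArm(sum(!pr), cl$type[i], cl$non_param1[i],
                       cl$non_param2[i], clampMin[i])
    out[[cl$feature[i]]] <- x
  }
  if ("bmi" %in% names(out)) out$bmi_ge30 <- as.numeric(out$bmi >= 30)
  if ("age" %in% names(out)) out$age_60_75 <- as.numeric(out$age >= 60)

  ag <- spec@agatston
  scores <- matrix(0, n, nrow(ag), dimnames = list(NULL, ag$vessel))
  for (i in seq_len(nrow(ag))) {
    lg <- numeric(n)
    lg[pr] <- stats::rnorm(sum(pr), ag$pr_mean[i], ag$pr_sd[i])
    lg[!pr] <- stats::rnorm(sum(!pr), ag$non_mean[i], ag$non_sd[i])
    lg <- pmax(lg, 0)
    scores[, i] <- 10^lg - 1
  }
  total <- rowSums(scores)
  for (v in colnames(scores)) {
    out[[paste0(tolower(v), "_score")]] <- scores[, v]
    out[[paste0("log_", tolower(v), "_score")]] <- log10(scores[, v] + 1)
  }
  out$total_score <- total
  out$log_total_score <- log10(total + 1)
  out$diffusivity_index <- ifelse(total > 0,
                                  1 - apply(scores, 1, max) / total, 0)
  out$high_cac <- as.numeric(total > 1000)

  fo <- spec@fatomics
  for (i in seq_len(nrow(fo))) {
    x <- numeric(n)
    x[pr] <- stats::rnorm(sum(pr), fo$pr_mean[i], fo$pr_sd[i])
    x[!pr] <- stats::rnorm(sum(!pr), fo$non_mean[i], fo$non_sd[i])
    if (isTRUE(fo$clamp01[i] == 1)) x <- pmin(pmax(x, 0), 1)
    out[[fo$feature[i]]] <- x
  }

  # exponential event times; PR multiplies the hazard by exp(logHr)
  rate <- spec@baselineHazard * exp(spec@logHr * pr)
  eventTime <- stats::rexp(n, rate)
  censTime <- rep(spec@followupYears, n)
  early <- stats::runif(n) < spec@censorRate
  censTime[early] <- stats::runif(sum(early), 0, spec@followupYears)
  out$time_years <- pmin(eventTime, censTime)
  out$event <- as.numeric(eventTime <= censTime)

  if (spec@missingRate > 0) {
    for (f in cl$feature) {
      miss <- stats::runif(n) < spec@missingRate
      out[[f]][miss] <- NA
    }
  }
  out
}

.isBinaryCol <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

#' Arm-wise group comparison of a cohort
#'
#' Compares PR-positive and PR-negative arms covariate by covariate:
#' Student's t-test for continuous covariates (mean +/- SD per arm) and the
#' chi-square test for binary covariates (count and percentage per arm),
#' mirroring a baseline-characteristics table. A covariate constant in both
#' arms is reported with p = 1 when the arms agree (and 0 when they differ);
#' a binary covariate with an empty margin is reported as not applicable.
#'
#' @param cohort A cohort data frame from [generateCohort()].
#' @param covariates Character vector of columns to compare; defaults to all
#'   feature columns (everything except id, label, and survival columns).
#' @return A data frame with columns `feature`, `type`, `pr_pos`, `pr_neg`
#'   (formatted arm summaries), and `p_value`.
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 400, seed = 2))
#' head(summarizeCohort(cohort))
#' @export
summarizeCohort <- function(cohort, covariates = NULL) {
  stopifnot(is.data.frame(cohort), "pr" %in% names(cohort))
  arms <- cohort$pr
  if (!any(arms) || all(arms))
    stop("both PR arms must be non-empty")
  if (is.null(covariates))
    covariates <- setdiff(names(cohort),
                          c("patient_id", "pr", "time_years", "event"))
  rows <- lapply(covariates, function(f) {
    x <- cohort[[f]]
    a <- x[arms & !is.na(x)]
    b <- x[!arms & !is.na(x)]
    if (.isBinaryCol(x)) {
      tab <- rbind(c(sum(a == 1), sum(a == 0)), c(sum(b == 1), sum(b == 0)))
      p <- if (length(unique(c(a, b))) <= 1) 1  # constant in both arms
           else if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) NA_real_
           else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      data.frame(feature = f, type = "binary",
                 pr_pos = sprintf("%d/%d (%.1f%%)", sum(a == 1), length(a),
                                  100 * mean(a)),
                 pr_neg = sprintf("%d/%d (%.1f%%)", sum(b == 1), length(b),
                                  100 * mean(b)),
                 p_value = p)
    } else {
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
      data.frame(feature = f, type = "continuous",
                 pr_pos = sprintf("%.2f ± %.2f", mean(a), stats::sd(a)),
                 pr_neg = sprintf("%.2f ± %.2f", mean(b), stats::sd(b)),
                 p_value = p)
    }
  })
  do.call(rbind, rows)
}
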