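#' Kaplan-Meier stratification with a log-rank test
#'
#' Product-limit survival estimates per group with 95% confidence bands and
#' a two-sided log-rank test between the two groups. With a single group the
#' curves are returned and the log-rank p is NA.
#'
#' @param time Follow-up duration per patient (years), >= 0.
#' @param event Event indicator (1 = MACE observed, 0 = censored).
#' @param group Logical or two-level covariate (e.g. predicted or actual PR).
#' @return List with `curves` (data frame: `group`, `time`, `surv`, `lower`,
#'   `upper`, `n_risk`) and `logrank_p`.
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 300, seed = 1))
#' km <- kmFit(cohort$time_years, cohort$event, cohort$pr)
#' km$logrank_p
#' @export
kmFit <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time >= 0))
  group <- factor(group)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.type = "log-log")
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper,
                       n_risk = fit$n.risk)
  logrankP <- NA_real_
  if (nlevels(droplevels(group)) >= 2 && sum(event) > 0) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    logrankP <- stats::pchisq(sd$chisq, df = length(sd$n) - 1,
                              lower.tail = FALSE)
  }
  list(curves = curves, logrank_p = logrankP)
}

#' Cox proportional-hazards fit for a binary risk group
#'
#' Partial-likelihood fit (Efron tie handling by default) of MACE hazard on
#' a binary covariate such as actual or predicted PR. Reports the hazard
#' ratio with its Wald 95% confidence interval, Harrell's concordance index,
#' and the Wald p-value. Complete separation (monotone likelihood) is
#' reported as an explicit error rather than a spuriously converged fit.
#'
#' @param time Follow-up duration (years).
#' @param event Event indicator.
#' @param group Logical/binary covariate.
#' @param ties Tie-handling method: `"efron"` (default) or `"breslow"`.
#' @return List with `hr`, `ci_low`, `ci_high`, `log_hr`, `se_log_hr`,
#'   `c_index`, `p_value`, and the underlying `coxph` fit.
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 500, seed = 1))
#' coxFit(cohort$time_years, cohort$event, cohort$pr)$hr
#' @export
coxFit <- function(time, event, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time >= 0))
  g <- as.numeric(as.logical(group))
  if (length(unique(g)) < 2) stop("both groups must be represented")
  if (sum(event[g == 1]) == 0 || sum(event[g == 0]) == 0)
    stop("no events in one group: Cox fit cannot converge (complete separation)")
  df <- data.frame(time = time, event = event, g = g)
  fit <- survival::coxph(survival::Surv(time, event) ~ g, data = df,
                         ties = ties)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || abs(beta) > 20)
    stop("Cox fit did not converge (monotone likelihood)")
  ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  list(hr = exp(beta), ci_low = ci[1], ci_high = ci[2], log_hr = beta,
       se_log_hr = se,
       c_index = unname(fit$concordance["concordance"]),
       p_value = unname(summary(fit)$coefficients[1, "Pr(>|z|)"]),
       fit = fit)
}
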