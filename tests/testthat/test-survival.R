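test_that("with no events both survival curves stay at 1", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(0, 6)
  group <- rep(c(TRUE, FALSE), 3)
  km <- kmFit(time, event, group)
  expect_true(all(km$curves$surv == 1))
  expect_true(is.na(km$logrank_p))
})

test_that("identical event patterns in the two groups give log-rank p = 1", {
  time <- rep(c(1, 2, 3, 4, 5), 2)
  event <- rep(c(1, 0, 1, 1, 0), 2)
  group <- rep(c(TRUE, FALSE), each = 5)
  km <- kmFit(time, event, group)
  expect_equal(km$logrank_p, 1)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(13)
  time <- rexp(60, 0.3)
  event <- rep(1, 60)
  km <- kmFit(time, event, rep(TRUE, 60))
  emp <- vapply(km$curves$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$curves$surv, emp, tolerance = 1e-12)
})

test_that("a hazard ratio of 3 is overwhelmingly detected at n = 5000", {
  coh <- generateCohort(cohortSpec(nPatients = 5000, logHr = log(3),
                                   seed = 17))
  km <- kmFit(coh$time_years, coh$event, coh$pr)
  expect_lt(km$logrank_p, 1e-5)
})

test_that("the generator's hazard ratio is recovered by the Cox fit", {
  coh <- generateCohort(cohortSpec(nPatients = 10000, logHr = log(6.5),
                                   seed = 23))
  fit <- coxFit(coh$time_years, coh$event, coh$pr)
  expect_lt(abs(fit$hr - 6.5) / 6.5, 0.10)
  expect_lte(fit$ci_low, fit$hr)
  expect_gte(fit$ci_high, fit$hr)
  expect_gt(fit$c_index, 0.5)
  expect_lt(fit$p_value, 1e-10)
})

test_that("the reported C-index matches a brute-force pairwise count", {
  # independent oracle: Harrell's C by O(n^2) enumeration, tied-predictor
  # comparable pairs counted one half
  harrellC <- function(time, event, risk) {
    conc <- 0; comp <- 0
    n <- length(time)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || event[i] != 1 || time[i] >= time[j]) next
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
    conc / comp
  }
  coh <- generateCohort(cohortSpec(nPatients = 120, seed = 37))
  fit <- coxFit(coh$time_years, coh$event, coh$pr)
  expect_equal(unname(fit$c_index),
               harrellC(coh$time_years, coh$event, as.numeric(coh$pr)),
               tolerance = 1e-10)
})

test_that("complete separation of events is reported, not silently fitted", {
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  group <- rep(c(TRUE, FALSE), each = 4)
  expect_error(coxFit(time, event, group), "separation|converge")
})

test_that("the Cox HR for a binary covariate ignores the time unit", {
  coh <- generateCohort(cohortSpec(nPatients = 2000, seed = 29))
  f1 <- coxFit(coh$time_years, coh$event, coh$pr)
  f2 <- coxFit(coh$time_years * 365.25, coh$event, coh$pr)
  expect_equal(f1$hr, f2$hr, tolerance = 1e-8)
  expect_equal(f1$c_index, f2$c_index, tolerance = 1e-12)
})

test_that("tie handling can switch between Efron and Breslow", {
  time <- c(1, 1, 1, 2, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  fe <- coxFit(time, event, group, ties = "efron")
  fb <- coxFit(time, event, group, ties = "breslow")
  expect_false(isTRUE(all.equal(fe$log_hr, fb$log_hr)))
})

test_that("degenerate survival inputs are rejected", {
  expect_error(coxFit(c(1, 2), c(1, 1), c(TRUE, TRUE)), "both groups")
  expect_error(coxFit(c(-1, 2), c(1, 1), c(TRUE, FALSE)), ">= 0")
})

test_that("fitted log-HR is unbiased over repeated cohorts", {
  ests <- ses <- numeric(40)
  for (i in seq_len(40)) {
    coh <- generateCohort(cohortSpec(nPatients = 2000, seed = 100 + i))
    fit <- coxFit(coh$time_years, coh$event, coh$pr)
    ests[i] <- fit$log_hr
    ses[i] <- fit$se_log_hr
  }
  seMean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - log(6.5)), 3 * seMean)
})
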