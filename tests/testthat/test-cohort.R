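bigCohort <- NULL
getBigCohort <- function() {
  if (is.null(bigCohort))
    bigCohort <<- generateCohort(cohortSpec(nPatients = 20000L, seed = 20L))
  bigCohort
}

test_that("cohort generation is reproducible and respects the spec", {
  a <- generateCohort(cohortSpec(nPatients = 150, seed = 9))
  b <- generateCohort(cohortSpec(nPatients = 150, seed = 9))
  expect_identical(a, b)
  expect_equal(nrow(a), 150L)
  expect_true(all(c("pr", "age", "male", "total_score", "log_total_score",
                    "diffusivity_index", "high_cac", "SR4_Pro_90_70",
                    "time_years", "event") %in% names(a)))
  # 23 clinical, 12 agatston-derived, 10 fat-omics columns
  ft <- buildFeatureTable(a)
  expect_equal(as.integer(table(featureClass(ft))[c("clinical", "agatston",
                                                    "fatomics")]),
               c(23L, 12L, 10L))
})

test_that("empirical prevalence matches the Bernoulli parameter at large n", {
  coh <- getBigCohort()
  se <- sqrt(0.324 * 0.676 / 20000)
  expect_lt(abs(mean(coh$pr) - 0.324), 3 * se)
})

test_that("arm-wise covariate moments track the calibration at large n", {
  coh <- getBigCohort()
  expect_lt(abs(mean(coh$age[coh$pr]) - 60.5), 0.3)
  expect_lt(abs(mean(coh$age[!coh$pr]) - 55.7), 0.3)
  expect_lt(abs(mean(coh$male[coh$pr]) - 0.737), 0.02)
  expect_lt(abs(mean(coh$male[!coh$pr]) - 0.470), 0.02)
  # log-scale Agatston separation in the right direction and magnitude
  expect_gt(mean(coh$log_total_score[coh$pr]),
            mean(coh$log_total_score[!coh$pr]) + 1)
  # derived band is consistent with its continuous source
  expect_identical(coh$bmi_ge30, as.numeric(coh$bmi >= 30))
})

test_that("agatston-derived columns satisfy the panel identities", {
  coh <- generateCohort(cohortSpec(nPatients = 400, seed = 12))
  expect_equal(coh$total_score,
               coh$lm_score + coh$lad_score + coh$lcx_score + coh$rca_score,
               tolerance = 1e-9)
  expect_equal(coh$log_total_score, log10(coh$total_score + 1),
               tolerance = 1e-12)
  expect_true(all(coh$diffusivity_index >= 0 & coh$diffusivity_index < 1))
  expect_identical(coh$high_cac, as.numeric(coh$total_score > 1000))
})

test_that("degenerate distribution parameters are rejected", {
  cl <- ctcsPR:::.calibration("clinical")
  cl$pr_param2[cl$type == "continuous"][1] <- -1
  expect_error(cohortSpec(clinical = cl), "non-negative")
  clBad <- ctcsPR:::.calibration("clinical")
  clBad$pr_param1[clBad$type == "binary"][1] <- 1.4
  expect_error(cohortSpec(clinical = clBad), "\\[0, 1\\]")
  expect_error(cohortSpec(prPrevalence = 0), "strictly")
  expect_error(cohortSpec(baselineHazard = -0.1), "positive")
})

test_that("missing-at-random masking only touches clinical covariates", {
  coh <- generateCohort(cohortSpec(nPatients = 1000, missingRate = 0.08,
                                   seed = 2))
  miss <- mean(is.na(coh$hypertension))
  expect_gt(miss, 0.04)
  expect_lt(miss, 0.13)
  expect_false(anyNA(coh$total_score))
  expect_false(anyNA(coh$time_years))
})

test_that("the group-comparison table mirrors the two-arm layout", {
  coh <- generateCohort(cohortSpec(nPatients = 800, seed = 7))
  tab <- summarizeCohort(coh)
  expect_named(tab, c("feature", "type", "pr_pos", "pr_neg", "p_value"))
  expect_true(all(tab$type %in% c("binary", "continuous")))
  expect_true(grepl("±", tab$pr_pos[tab$feature == "age"]))
  expect_true(grepl("%", tab$pr_pos[tab$feature == "male"]))
  # strongly separated covariates are detected
  expect_lt(tab$p_value[tab$feature == "log_total_score"], 1e-10)
})

test_that("a covariate constant in both arms reports p = 1", {
  coh <- generateCohort(cohortSpec(nPatients = 120, seed = 4))
  coh$constant_cont <- 5.5
  coh$constant_bin <- 1
  tab <- summarizeCohort(coh, c("constant_cont", "constant_bin"))
  expect_equal(tab$p_value, c(1, 1))
})

test_that("the published male split is overwhelmingly significant", {
  coh <- data.frame(pr = rep(c(TRUE, FALSE), c(429, 895)),
                    male = c(rep(c(1, 0), c(316, 429 - 316)),
                             rep(c(1, 0), c(421, 895 - 421))))
  tab <- summarizeCohort(coh, "male")
  expect_lt(tab$p_value, 1e-5)
})

test_that("null arms give approximately uniform p-values", {
  pvals <- c()
  for (seed in 1:30) {
    coh <- generateCohort(plantedCohortSpec(nPatients = 400, seed = seed))
    tab <- summarizeCohort(coh)
    clinical <- ctcsPR:::.calibration("clinical")$feature
    pvals <- c(pvals, tab$p_value[tab$feature %in% clinical])
  }
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})

test_that("a null hazard ratio is recovered as no group effect", {
  coh <- generateCohort(cohortSpec(nPatients = 4000, logHr = 0, seed = 31))
  fit <- coxFit(coh$time_years, coh$event, coh$pr)
  expect_lt(fit$ci_low, 1)
  expect_gt(fit$ci_high, 1)
  expect_lt(abs(fit$c_index - 0.5), 0.03)
})
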