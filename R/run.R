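#' Default end-to-end run configuration
#'
#' @return Named list of stage parameters: cohort size, PR prevalence,
#'   phantom seed, fat-omics window settings, classifier backend and
#'   model numbers, CV repetitions/folds, and the master seed.
#' @export
defaultRunConfig <- function() {
  list(seed = 1L,
       cohort = list(n_patients = 600L, pr_prevalence = 0.324,
                     missing_rate = 0),
       phantom = list(enabled = TRUE),
       fatomics = list(n_ribbons = 5L),
       pipeline = list(models = c(1L, 2L, 3L), backend = "gbdt",
                       n_repetitions = 5L, n_folds = 5L,
                       selection = "per-fold", threshold = 0.5),
       survival = list(split = "predicted-label"))
}

#' Read a run configuration from YAML
#'
#' Unknown top-level keys are rejected; omitted keys take the defaults of
#' [defaultRunConfig()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  utils::modifyList(def, cfg)
}

#' Run the full analysis end to end
#'
#' Orchestrates every stage on synthetic data: a demonstration phantom is
#' scored (Agatston panel) and fat-omics features are extracted from it; a
#' cohort is simulated and summarized arm by arm; the feature table is
#' assembled; elastic-net selection and repeated stratified cross-validation
#' are run for the requested model groupings; adjacent models are compared
#' (McNemar/DeLong); and Kaplan-Meier/Cox fits are produced for the actual
#' and the cross-validated predicted PR labels. All tables are written under
#' `outDir` together with a manifest recording the configuration hash, the
#' seeds, and the package version.
#'
#' @param config Configuration list, see [defaultRunConfig()]; a YAML path
#'   is also accepted.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `cohortSummary`,
#'   `panel`, `fatomics`, `selection`, `cv` (per model), `comparisons`,
#'   `survival`, `manifest`.
#' @export
runEndToEnd <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- utils::modifyList(defaultRunConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stage <- "configuration"
  fail <- function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE)

  res <- list()
  tryCatch({
    stage <- "phantom"
    if (isTRUE(cfg$phantom$enabled)) {
      ph <- generatePhantom(phantomSpec(
        lesions = list(lesionSpec("LAD", center = c(23, 23, 21), radius = 3,
                                  peakHu = 450),
                       lesionSpec("RCA", center = c(30, 16, 27), radius = 2.5,
                                  peakHu = 300)),
        seed = seed))
      res$panel <- scoreVolume(ph$volume, ph$territories)
      utils::write.csv(as.data.frame(res$panel),
                       file.path(outDir, "phantom_agatston_panel.csv"),
                       row.names = FALSE)
      stage <- "fatomics"
      geo <- assignSlabsRibbons(ph$eat, ph$pericardium,
                                nRibbons = cfg$fatomics$n_ribbons)
      res$fatomics <- extractFeatures(ph$volume, geo)
      utils::write.csv(data.frame(feature = names(res$fatomics),
                                  value = unname(res$fatomics)),
                       file.path(outDir, "phantom_fatomics.csv"),
                       row.names = FALSE)
    }

    stage <- "cohort"
    spec <- cohortSpec(nPatients = cfg$cohort$n_patients,
                       prPrevalence = cfg$cohort$pr_prevalence,
                       missingRate = cfg$cohort$missing_rate,
                       seed = seed)
    cohort <- generateCohort(spec)
    writeCohort(cohort, file.path(outDir, "cohort.csv"))
    res$cohortSummary <- summarizeCohort(cohort)
    utils::write.csv(res$cohortSummary,
                     file.path(outDir, "cohort_summary.csv"),
                     row.names = FALSE)

    stage <- "feature table"
    ft <- buildFeatureTable(cohort)
    writeFeatureTable(ft, file.path(outDir, "features"))

    stage <- "feature selection"
    res$selection <- selectFeatures(ft, model = max(cfg$pipeline$models),
                                    seed = seed)
    utils::write.csv(res$selection@selected,
                     file.path(outDir, "selected_features.csv"),
                     row.names = FALSE)

    stage <- "cross-validation"
    res$cv <- list()
    metricRows <- list()
    for (m in cfg$pipeline$models) {
      cv <- crossValidate(ft, model = m, backend = cfg$pipeline$backend,
                          nRepetitions = cfg$pipeline$n_repetitions,
                          nFolds = cfg$pipeline$n_folds, seed = seed,
                          selection = cfg$pipeline$selection,
                          threshold = cfg$pipeline$threshold)
      res$cv[[as.character(m)]] <- cv
      s <- summary(cv)
      metricRows[[length(metricRows) + 1L]] <- data.frame(
        model = m,
        metric = rownames(s), mean_pct = s$mean, sd_pct = s$sd)
    }
    utils::write.csv(do.call(rbind, metricRows),
                     file.path(outDir, "cv_metrics.csv"), row.names = FALSE)

    stage <- "model comparison"
    res$comparisons <- list()
    ms <- as.character(cfg$pipeline$models)
    if (length(ms) > 1) {
      for (i in seq_len(length(ms) - 1)) {
        cmp <- compareModels(res$cv[[ms[i]]], res$cv[[ms[i + 1]]])
        res$comparisons[[paste0("m", ms[i], "_vs_m", ms[i + 1])]] <- cmp
      }
      utils::write.csv(
        do.call(rbind, lapply(names(res$comparisons), function(nm)
          data.frame(comparison = nm,
                     mcnemar_p = res$comparisons[[nm]]$mcnemar_p,
                     delong_p = res$comparisons[[nm]]$delong_p,
                     auc_a = res$comparisons[[nm]]$auc_a,
                     auc_b = res$comparisons[[nm]]$auc_b))),
        file.path(outDir, "model_comparisons.csv"), row.names = FALSE)
    }

    stage <- "survival"
    bestCv <- res$cv[[as.character(max(cfg$pipeline$models))]]
    scores <- rowMeans(bestCv@oofScores, na.rm = TRUE)
    predicted <- if (identical(cfg$survival$split, "median-risk"))
      scores > stats::median(scores)
    else scores >= cfg$pipeline$threshold
    res$survival <- list(
      actual = coxFit(cohort$time_years, cohort$event, cohort$pr),
      predicted = coxFit(cohort$time_years, cohort$event, predicted),
      km_actual = kmFit(cohort$time_years, cohort$event, cohort$pr),
      km_predicted = kmFit(cohort$time_years, cohort$event, predicted))
    survRows <- do.call(rbind, lapply(c("actual", "predicted"), function(w) {
      f <- res$survival[[w]]
      data.frame(covariate = paste(w, "PR"), hr = f$hr, ci_low = f$ci_low,
                 ci_high = f$ci_high, c_index = f$c_index,
                 p_value = f$p_value,
                 logrank_p = res$survival[[paste0("km_", w)]]$logrank_p)
    }))
    utils::write.csv(survRows, file.path(outDir, "survival_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(res$survival$km_predicted$curves,
                     file.path(outDir, "km_curves_predicted.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    manifest <- list(config_md5 = unname(tools::md5sum(cfgPath)),
                     seed = seed,
                     package_version =
                       as.character(utils::packageVersion("ctcsPR")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }, error = fail)
  invisible(res)
}
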