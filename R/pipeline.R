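#' Stratified cross-validation folds
#'
#' Assigns each patient to one of `nFolds` validation folds, stratified by
#' class: within each class, shuffled indices are dealt round-robin, so every
#' fold's class ratio is within one patient of the global ratio and the folds
#' partition the cohort.
#'
#' @param labels Logical class labels.
#' @param nFolds Number of folds (>= 2).
#' @param seed Integer RNG seed.
#' @return Integer fold id (1..nFolds) per patient.
#' @export
makeStratifiedFolds <- function(labels, nFolds = 5L, seed = 1L) {
  stopifnot(nFolds >= 2L)
  if (min(table(labels)) < nFolds)
    stop("each class must have at least nFolds members")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

# Median imputation: medians learned on the training rows only.
.imputeMedian <- function(xTrain, xTest = NULL) {
  med <- apply(xTrain, 2, stats::median, na.rm = TRUE)
  fill <- function(x) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- med[j]
    }
    x
  }
  list(train = fill(xTrain), test = if (!is.null(xTest)) fill(xTest))
}

#' Elastic-net feature selection
#'
#' Penalized logistic regression with mixing parameter `alpha` (default 0.5,
#' an equal balance of lasso and ridge penalties) over a path of `nLambda`
#' log-spaced regularization values, the largest of which zeroes every
#' coefficient. The penalty is chosen by `nFolds`-fold cross-validation;
#' features with nonzero coefficients at the optimal penalty are returned
#' ordered by importance, the absolute standardized coefficient. Optional
#' bootstrap resampling (refitting at the chosen penalty) yields percentile
#' confidence intervals for the importances.
#'
#' @param table A [FeatureTable-class].
#' @param model Model grouping (1-3) defining the candidate features.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param nLambda Length of the regularization path.
#' @param nFolds Cross-validation folds for the penalty choice.
#' @param seed Integer RNG seed.
#' @param nBoot Bootstrap resamples for importance CIs (0 disables).
#' @return A [SelectionResult-class].
#' @examples
#' ft <- buildFeatureTable(generateCohort(cohortSpec(nPatients = 300)))
#' selectFeatures(ft, model = 2, seed = 1)
#' @export
selectFeatures <- function(table, model = 3, alpha = 0.5, nLambda = 100L,
                           nFolds = 5L, seed = 1L, nBoot = 0L) {
  stopifnot(is(table, "FeatureTable"), alpha >= 0, alpha <= 1)
  y <- prLabels(table)
  if (min(base::table(y)) < 2L) stop("need at least 2 patients per class")
  if (nFolds > min(base::table(y)))
    stop("nFolds exceeds the size of the smaller class")
  x <- designMatrix(table, model = model)
  x <- .imputeMedian(x)$train
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  set.seed(seed)
  foldid <- makeStratifiedFolds(y, nFolds, seed)
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                             nlambda = nLambda, foldid = foldid,
                             standardize = TRUE)
  fit <- cvfit$glmnet.fit
  co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
  names(co) <- colnames(x)
  imp <- abs(co) * sds
  keep <- which(co != 0)
  ord <- keep[order(imp[keep], decreasing = TRUE)]
  sel <- data.frame(feature = colnames(x)[ord], coefficient = unname(co[ord]),
                    importance = unname(imp[ord]),
                    ci_low = rep(NA_real_, length(ord)),
                    ci_high = rep(NA_real_, length(ord)), row.names = NULL)
  if (nBoot > 0 && nrow(sel)) {
    boot <- matrix(0, nBoot, ncol(x), dimnames = list(NULL, colnames(x)))
    for (b in seq_len(nBoot)) {
      repeat {
        ii <- sample.int(nrow(x), replace = TRUE)
        if (length(unique(y[ii])) == 2L) break
      }
      bs <- apply(x[ii, , drop = FALSE], 2, stats::sd)
      ok <- bs > 0
      bf <- glmnet::glmnet(x[ii, ok, drop = FALSE], y[ii],
                           family = "binomial", alpha = alpha,
                           lambda = cvfit$lambda.min, standardize = TRUE)
      bco <- as.numeric(stats::coef(bf))[-1]
      boot[b, ok] <- abs(bco) * bs[ok]
    }
    qs <- apply(boot[, sel$feature, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975))
    sel$ci_low <- qs[1, ]
    sel$ci_high <- qs[2, ]
  }
  new("SelectionResult", selected = sel, alpha = alpha,
      lambdaPath = fit$lambda, lambdaOpt = cvfit$lambda.min,
      nzeroPath = as.integer(fit$df))
}

BACKENDS <- c("gbdt", "randomForest", "svm", "xgboost")

#' Default gradient-boosted-tree hyperparameters
#'
#' 100 iterations, learning rate 0.01, tree depth 6, L2 leaf regularization
#' 3, per-tree feature subsampling 0.75, 64 histogram bins, logloss
#' objective, Bernoulli row subsampling at rate 0.6, single thread.
#'
#' @return Named list of hyperparameters.
#' @export
gbdtHyperparams <- function() {
  list(iterations = 100L, learning_rate = 0.01, depth = 6L,
       l2_leaf_reg = 3, rsm = 0.75, border_count = 64L,
       loss_function = "logloss", bootstrap_type = "Bernoulli",
       subsample = 0.6, thread_count = 1L)
}

.fitBackend <- function(backend, x, y, hyperparams, seed) {
  set.seed(seed)
  switch(backend,
    gbdt = {
      hp <- utils::modifyList(gbdtHyperparams(), hyperparams)
      params <- list(objective = "binary:logistic", eta = hp$learning_rate,
                     max_depth = hp$depth, lambda = hp$l2_leaf_reg,
                     colsample_bytree = hp$rsm, max_bin = hp$border_count,
                     subsample = hp$subsample, tree_method = "hist",
                     nthread = hp$thread_count, seed = seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$iterations, verbose = 0)
    },
    xgboost = {
      hp <- utils::modifyList(list(nrounds = 100L, eta = 0.3, max_depth = 6L),
                              hyperparams)
      params <- list(objective = "binary:logistic", eta = hp$eta,
                     max_depth = hp$max_depth, nthread = 1L, seed = seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds, verbose = 0)
    },
    randomForest = {
      hp <- utils::modifyList(list(ntree = 500L), hyperparams)
      randomForest::randomForest(x, factor(y, levels = c(FALSE, TRUE)),
                                 ntree = hp$ntree)
    },
    svm = {
      hp <- utils::modifyList(list(kernel = "radial", cost = 1), hyperparams)
      e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = hp$kernel,
                 cost = hp$cost, probability = TRUE)
    },
    stop(sprintf("unknown backend '%s'", backend)))
}

.predictBackend <- function(backend, fit, x) {
  switch(backend,
    gbdt = ,
    xgboost = stats::predict(fit, xgboost::xgb.DMatrix(x)),
    randomForest = stats::predict(fit, x, type = "prob")[, "TRUE"],
    svm = {
      p <- stats::predict(fit, x, probability = TRUE)
      attr(p, "probabilities")[, "TRUE"]
    })
}

#' Train a PR classifier
#'
#' Fits a binary classifier for the PR label on a chosen feature subset.
#' The default backend is a gradient-boosted tree ensemble with the
#' hyperparameters of [gbdtHyperparams()]; random forest, RBF-kernel SVM,
#' and a conventionally tuned boosted-tree backend are available for model
#' comparison. Missing feature values are median-imputed (medians fit on the
#' training data). Deterministic for a given seed.
#'
#' @param table A [FeatureTable-class].
#' @param features Feature names to use; defaults to all Model-3 features.
#' @param backend One of `"gbdt"`, `"randomForest"`, `"svm"`, `"xgboost"`.
#' @param hyperparams Named list overriding backend defaults.
#' @param seed Integer RNG seed.
#' @return An object of class `PRClassifier`: a list with the fitted model,
#'   backend, feature names, and training medians; use [stats::predict()] to
#'   obtain class probabilities for a [FeatureTable-class].
#' @examples
#' ft <- buildFeatureTable(generateCohort(cohortSpec(nPatients = 200)))
#' clf <- trainClassifier(ft, seed = 1)
#' head(predict(clf, ft))
#' @export
trainClassifier <- function(table, features = NULL,
                            backend = c("gbdt", "randomForest", "svm",
                                        "xgboost"),
                            hyperparams = list(), seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(is(table, "FeatureTable"))
  if (is.null(features)) features <- modelFeatures(table, 3)
  x <- designMatrix(table, features)
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  x <- .imputeMedian(x)$train
  fit <- .fitBackend(backend, x, prLabels(table), hyperparams, seed)
  structure(list(fit = fit, backend = backend, features = features,
                 medians = med, seed = seed),
            class = "PRClassifier")
}

#' @rdname trainClassifier
#' @param object A `PRClassifier`.
#' @param newdata A [FeatureTable-class] (or patients-by-features matrix).
#' @param ... Ignored.
#' @export
predict.PRClassifier <- function(object, newdata, ...) {
  x <- if (is(newdata, "FeatureTable")) designMatrix(newdata, object$features)
       else newdata[, object$features, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- object$medians[j]
  }
  .predictBackend(object$backend, object$fit, x)
}

#' Classification metrics at a fixed operating threshold
#'
#' Sensitivity, specificity, and accuracy at the given probability threshold
#' (default 0.5), plus the AUC of the score ranking.
#'
#' @param labels Logical true labels.
#' @param scores Predicted probabilities.
#' @param threshold Operating threshold on the probability.
#' @return Named numeric: `sensitivity`, `specificity`, `accuracy`, `auc`
#'   (proportions in \[0, 1\]).
#' @examples
#' classificationMetrics(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.4, 0.2, 0.6))
#' @export
classificationMetrics <- function(labels, scores, threshold = 0.5) {
  pred <- scores >= threshold
  sens <- if (any(labels)) mean(pred[labels]) else NA_real_
  spec <- if (any(!labels)) mean(!pred[!labels]) else NA_real_
  acc <- mean(pred == labels)
  auc <- if (any(labels) && any(!labels))
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   levels = c(FALSE, TRUE),
                                   direction = "<")))
  else NA_real_
  c(sensitivity = sens, specificity = spec, accuracy = acc, auc = auc)
}

#' Repeated stratified cross-validation
#'
#' Evaluates a model grouping by repeated stratified k-fold
#' cross-validation. Within each repetition the cohort is partitioned into
#' stratified folds; the classifier (and, in the default leak-free mode, the
#' elastic-net feature selection) is fit on the training folds and scored on
#' the held-out fold. Sensitivity/specificity/accuracy use a fixed operating
#' threshold of 0.5 on the predicted probability.
#'
#' @param table A [FeatureTable-class].
#' @param model Model grouping (1-3).
#' @param backend Classifier backend, see [trainClassifier()].
#' @param nRepetitions Number of CV repetitions.
#' @param nFolds Folds per repetition.
#' @param seed Integer RNG seed.
#' @param selection `"per-fold"` re-runs feature selection inside each
#'   training fold (leak-free, default); `"once"` selects once on the full
#'   table before cross-validation; `"none"` uses all model features.
#' @param threshold Operating threshold for sensitivity/specificity.
#' @param hyperparams Passed to the backend.
#' @param selectionArgs Named list passed to [selectFeatures()].
#' @return A [CVEvaluation-class].
#' @examples
#' ft <- buildFeatureTable(generateCohort(cohortSpec(nPatients = 200)))
#' cv <- crossValidate(ft, model = 2, nRepetitions = 2, selection = "none")
#' summary(cv)
#' @export
crossValidate <- function(table, model = 3,
                          backend = c("gbdt", "randomForest", "svm",
                                      "xgboost"),
                          nRepetitions = 25L, nFolds = 5L, seed = 1L,
                          selection = c("per-fold", "once", "none"),
                          threshold = 0.5, hyperparams = list(),
                          selectionArgs = list()) {
  backend <- match.arg(backend)
  selection <- match.arg(selection)
  stopifnot(is(table, "FeatureTable"), nFolds >= 2L)
  y <- prLabels(table)
  n <- ncol(table)
  allFeatures <- modelFeatures(table, model)

  onceFeatures <- NULL
  if (selection == "once") {
    selArgs <- utils::modifyList(list(table = table, model = model,
                                      seed = seed), selectionArgs)
    onceFeatures <- do.call(selectFeatures, selArgs)@selected$feature
    if (!length(onceFeatures)) onceFeatures <- allFeatures
  }

  oof <- matrix(NA_real_, n, nRepetitions)
  perRep <- vector("list", nRepetitions)
  for (r in seq_len(nRepetitions)) {
    repSeed <- seed + r - 1L
    fold <- makeStratifiedFolds(y, nFolds, repSeed)
    for (k in seq_len(nFolds)) {
      trIdx <- which(fold != k)
      teIdx <- which(fold == k)
      trTable <- table[, trIdx]
      feats <- switch(selection,
        "per-fold" = {
          selArgs <- utils::modifyList(
            list(table = trTable, model = model,
                 seed = repSeed * 131L + k), selectionArgs)
          f <- do.call(selectFeatures, selArgs)@selected$feature
          if (length(f)) f else allFeatures
        },
        "once" = onceFeatures,
        "none" = allFeatures)
      clf <- trainClassifier(trTable, features = feats, backend = backend,
                             hyperparams = hyperparams,
                             seed = repSeed * 977L + k)
      oof[teIdx, r] <- predict(clf, table[, teIdx])
    }
    perRep[[r]] <- c(repetition = r,
                     classificationMetrics(y, oof[, r], threshold))
  }
  new("CVEvaluation",
      perRepetition = as.data.frame(do.call(rbind, perRep)),
      oofScores = oof, labels = y, nRepetitions = as.integer(nRepetitions),
      nFolds = as.integer(nFolds), model = as.integer(model),
      backend = backend)
}

#' @describeIn crossValidate Mean and SD of each metric over repetitions,
#'   as percentages.
#' @param object A [CVEvaluation-class].
#' @export
setMethod("summary", "CVEvaluation", function(object, ...) {
  m <- object@perRepetition[c("sensitivity", "specificity", "accuracy",
                              "auc")]
  out <- data.frame(mean = 100 * colMeans(m, na.rm = TRUE),
                    sd = 100 * apply(m, 2, stats::sd, na.rm = TRUE))
  out
})

#' Compare two classifiers on shared out-of-fold predictions
#'
#' McNemar's chi-square test (without continuity correction) on the
#' discordant pairs of correct/incorrect calls at the operating threshold,
#' and DeLong's test for the difference in AUC. The two prediction vectors
#' must score the same patients; [CVEvaluation-class] objects are reduced to
#' their per-patient mean out-of-fold score. With zero discordant pairs the
#' McNemar p-value is 1 by convention.
#'
#' @param evalA,evalB Numeric score vectors or [CVEvaluation-class] objects
#'   evaluated on the same cohort.
#' @param labels Logical true labels (taken from `evalA` if it is a
#'   [CVEvaluation-class]).
#' @param threshold Operating threshold.
#' @return List with `mcnemar_p`, `mcnemar_statistic`, `delong_p`,
#'   `auc_a`, `auc_b`.
#' @export
compareModels <- function(evalA, evalB, labels = NULL, threshold = 0.5) {
  scoreOf <- function(e) {
    if (is(e, "CVEvaluation")) rowMeans(e@oofScores, na.rm = TRUE)
    else as.numeric(e)
  }
  if (is.null(labels)) {
    stopifnot(is(evalA, "CVEvaluation"))
    labels <- evalA@labels
  }
  a <- scoreOf(evalA)
  b <- scoreOf(evalB)
  stopifnot(length(a) == length(b), length(a) == length(labels))
  corrA <- (a >= threshold) == labels
  corrB <- (b >= threshold) == labels
  n01 <- sum(corrA & !corrB)
  n10 <- sum(!corrA & corrB)
  if (n01 + n10 == 0) {
    mcP <- 1
    mcStat <- 0
  } else {
    mcStat <- (n01 - n10)^2 / (n01 + n10)
    mcP <- stats::pchisq(mcStat, df = 1, lower.tail = FALSE)
  }
  rocA <- pROC::roc(labels, a, quiet = TRUE, levels = c(FALSE, TRUE),
                    direction = "<")
  rocB <- pROC::roc(labels, b, quiet = TRUE, levels = c(FALSE, TRUE),
                    direction = "<")
  dl <- if (isTRUE(all.equal(a, b))) list(p.value = 1)
        else pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  list(mcnemar_p = mcP, mcnemar_statistic = mcStat,
       delong_p = as.numeric(dl$p.value),
       auc_a = as.numeric(pROC::auc(rocA)),
       auc_b = as.numeric(pROC::auc(rocB)))
}
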