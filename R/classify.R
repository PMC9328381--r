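POSITIVE_CLASS <- "nonresponder"
NEGATIVE_CLASS <- "good"

#' Balanced accuracy
#'
#' Mean of per-class recalls; 0.5 for a degenerate all-one-class prediction
#' on two-class truth, robust to class imbalance.
#'
#' @param truth True labels (two classes, both present).
#' @param predicted Predicted labels over the same vocabulary.
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- sort(unique(truth))
  if (length(classes) < 2L)
    stopf("balanced accuracy undefined: only one class present in truth")
  recalls <- vapply(classes, function(cl)
    mean(predicted[truth == cl] == cl), numeric(1))
  mean(recalls)
}

#' Area under the ROC curve
#'
#' Probability that a random positive (nonresponder) scores above a random
#' negative, i.e. the Mann-Whitney U statistic normalized by `n_pos * n_neg`;
#' ties contribute 1/2.
#'
#' @param truth True labels; the positive class is `"nonresponder"` (or pass
#'   logicals where `TRUE` is positive).
#' @param scores Numeric classifier scores, higher = more nonresponder-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, scores) {
  pos <- if (is.logical(truth)) truth else as.character(truth) == POSITIVE_CLASS
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stopf("AUC undefined: both classes must be present")
  if (diff(range(scores)) == 0) {
    warnf("constant scores: AUC is 0.5 by convention")
    return(0.5)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold scores into class labels
#'
#' Predicts the positive class (`"nonresponder"`) where `score >= threshold`,
#' so raising the threshold never increases the positive count.
#'
#' @param scores Numeric scores.
#' @param threshold Decision threshold (default 0.5, the posterior midpoint
#'   for probabilistic families).
#' @return Character labels.
#' @export
threshold_prediction <- function(scores, threshold = 0.5) {
  ifelse(scores >= threshold, POSITIVE_CLASS, NEGATIVE_CLASS)
}

#' Nonresponder-detection trade-off curve
#'
#' Sweeps the decision threshold over pooled held-out scores and reports, for
#' each threshold, the fraction of true nonresponders detected against the
#' fraction of good responders misclassified as nonresponders.  This is the
#' clinically relevant reading of the ROC sweep when the goal is high recall
#' of nonresponders at an acceptable cost in misclassified responders.
#'
#' @param scores Pooled held-out scores (e.g., `$scores$score` of
#'   [nested_cv()]).
#' @param truth Matching labels.
#' @return Data frame with `threshold`, `detected_nonresponders`,
#'   `misclassified_good`, stepwise non-decreasing from (0,0) to (1,1).
#' @export
nonresponder_detection_curve <- function(scores, truth) {
  pos <- if (is.logical(truth)) truth else as.character(truth) == POSITIVE_CLASS
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  detected <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  miscl <- vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = thresholds, detected_nonresponders = detected,
             misclassified_good = miscl)
}

#' Aggregate gene-level features to pathway-level features
#'
#' Pathway-supported modeling proxy: each retained pathway becomes one
#' feature, the mean of its member genes' (already standardized) features.
#' Genes outside every retained pathway are dropped.  This is a deliberately
#' simple aggregation standing in for more elaborate pathway-supported
#' learners; it preserves the three-family model comparison.
#'
#' @param features A [feature_matrix()] (standardize first for comparability
#'   across genes).
#' @param pathways Named list: term -> character vector of member genes.
#' @param min_genes Minimum member genes present in `features` for a pathway
#'   to be retained (default 3).
#' @return A [feature_matrix()] of pathway-level features.
#' @export
pathway_aggregate <- function(features, pathways, min_genes = 3L) {
  stopifnot(inherits(features, "feature_matrix"))
  present <- lapply(pathways, intersect, y = features$feature_ids)
  keep <- lengths(present) >= min_genes
  if (!any(keep))
    stopf("no pathway has >= %d member genes among the features", min_genes)
  present <- present[keep]
  vals <- t(vapply(present, function(g)
    colMeans(features$values[g, , drop = FALSE]), numeric(ncol(features$values))))
  feature_matrix(vals, names(present), features$patient_ids,
                 features$contrast_tag)
}

#' Summarize per-fold linear model coefficients
#'
#' Mean and sample SD of each feature's coefficient across cross-validation
#' folds; the magnitude ordering of the means defines the reported
#' top-features table.
#'
#' @param coef_matrix Folds x features numeric matrix (NA where a feature was
#'   dropped in a fold).
#' @return Data frame `feature`, `mean`, `sd`, `n_folds`, sorted by
#'   decreasing `|mean|`.
#' @export
summarize_importance <- function(coef_matrix) {
  mu <- colMeans(coef_matrix, na.rm = TRUE)
  sdv <- apply(coef_matrix, 2L, stats::sd, na.rm = TRUE)
  n <- colSums(!is.na(coef_matrix))
  out <- data.frame(feature = colnames(coef_matrix), mean = mu, sd = sdv,
                    n_folds = n, row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$mean), out$feature), , drop = FALSE]
}

#' Model family specification
#'
#' Declares one of the three model families and its hyperparameter grid:
#' `l2_logistic` (ridge-penalized logistic regression; grid of 7 log-spaced
#' penalty strengths), `random_forest` (tree count x depth limit, with
#' `sqrt(p)` features per split), or `pathway_supported` (pathway mean
#' aggregation followed by the L2 family).
#'
#' @param family One of `"l2_logistic"`, `"random_forest"`,
#'   `"pathway_supported"`.
#' @param hyperparameter_grid Family-specific grid; `NULL` for defaults.  For
#'   linear families a list with `lambda`; for random forest a data frame
#'   with `ntree` and `max_depth` (NA = unlimited).
#' @param min_pathway_genes Pathway size floor for `pathway_supported`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("l2_logistic", "random_forest",
                                  "pathway_supported"),
                       hyperparameter_grid = NULL, min_pathway_genes = 3L) {
  family <- match.arg(family)
  if (is.null(hyperparameter_grid)) {
    hyperparameter_grid <- if (family == "random_forest") {
      expand.grid(ntree = c(200L, 500L), max_depth = c(NA_integer_, 8L))
    } else {
      list(lambda = 10^seq(3, -3, length.out = 7))
    }
  }
  if (family == "random_forest") {
    if (!nrow(hyperparameter_grid)) stopf("hyperparameter grid must be non-empty")
  } else if (!length(hyperparameter_grid$lambda)) {
    stopf("hyperparameter grid must contain at least one lambda")
  }
  structure(list(family = family, hyperparameter_grid = hyperparameter_grid,
                 inner_selection_metric = "roc_auc",
                 min_pathway_genes = min_pathway_genes),
            class = "model_spec")
}

# stratified k-fold assignment; uses the current RNG stream
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.as_glmnet_y <- function(labels) factor(labels, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))

# glmnet needs >= 2 columns; pad single-feature designs with a zero column
.pad_x <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `.pad.` = 0)
}

.fit_linear <- function(x, labels, lambda_grid) {
  glmnet::glmnet(.pad_x(x), .as_glmnet_y(labels), family = "binomial",
                 alpha = 0, lambda = sort(lambda_grid, decreasing = TRUE),
                 standardize = FALSE)
}

.predict_linear <- function(fit, x, lambda) {
  stats::predict(fit, newx = .pad_x(x), s = lambda, type = "response",
                 exact = FALSE)
}

.fit_rf <- function(x, labels, ntree, max_depth) {
  maxnodes <- if (is.na(max_depth)) NULL else 2L^as.integer(max_depth)
  randomForest::randomForest(
    x = x, y = .as_glmnet_y(labels), ntree = ntree,
    mtry = max(1L, floor(sqrt(ncol(x)))), maxnodes = maxnodes)
}

.predict_rf <- function(fit, x) {
  stats::predict(fit, newdata = x, type = "prob")[, POSITIVE_CLASS]
}

# inner k-fold hyperparameter selection on the (standardized) training data;
# returns the chosen hyperparameter (first maximum of mean inner AUC)
.inner_select <- function(x, labels, spec, k_inner) {
  folds <- .stratified_folds(labels, k_inner)
  if (spec$family == "random_forest") {
    grid <- spec$hyperparameter_grid
    auc <- matrix(NA_real_, k_inner, nrow(grid))
    for (f in seq_len(k_inner)) {
      tr <- folds != f
      if (length(unique(labels[!tr])) < 2L) next
      for (g in seq_len(nrow(grid))) {
        fit <- .fit_rf(x[tr, , drop = FALSE], labels[tr],
                       grid$ntree[g], grid$max_depth[g])
        auc[f, g] <- roc_auc(labels[!tr], .predict_rf(fit, x[!tr, , drop = FALSE]))
      }
    }
    mean_auc <- colMeans(auc, na.rm = TRUE)
    list(hyper = as.list(grid[which.max(mean_auc), , drop = FALSE]),
         inner_auc = mean_auc)
  } else {
    lambdas <- sort(spec$hyperparameter_grid$lambda, decreasing = TRUE)
    auc <- matrix(NA_real_, k_inner, length(lambdas))
    for (f in seq_len(k_inner)) {
      tr <- folds != f
      if (length(unique(labels[!tr])) < 2L) next
      fit <- .fit_linear(x[tr, , drop = FALSE], labels[tr], lambdas)
      pred <- .predict_linear(fit, x[!tr, , drop = FALSE], lambdas)
      for (g in seq_along(lambdas))
        auc[f, g] <- roc_auc(labels[!tr], pred[, g])
    }
    mean_auc <- colMeans(auc, na.rm = TRUE)
    list(hyper = list(lambda = lambdas[which.max(mean_auc)]),
         inner_auc = mean_auc)
  }
}

#' Nested cross-validated classification of nonresponse
#'
#' Estimates out-of-sample performance with a 10-fold outer / 5-fold inner
#' nested cross-validation: outer folds are stratified by response label;
#' within each outer training set, features are standardized (parameters
#' estimated on that training set only), hyperparameters are chosen by inner
#' stratified k-fold maximizing ROC AUC, the model is refit on the full
#' training set, and the held-out patients are scored once.  Nothing
#' estimated from data — standardization parameters, pathway aggregates,
#' hyperparameters — ever sees the held-out fold.
#'
#' @param features A [feature_matrix()].
#' @param labels Response per patient: named character vector
#'   (`good`/`nonresponder`) or vector aligned with the feature matrix's
#'   patients.
#' @param spec A [model_spec()].
#' @param k_outer,k_inner Fold counts (defaults 10 and 5).
#' @param seed Integer seed controlling fold assignment and any model
#'   randomness; per-outer-fold seeds are derived so folds are independently
#'   reproducible.
#' @param pathways Named list term -> genes; required for the
#'   `pathway_supported` family.
#' @return An object of class `cv_result`: `per_fold` (fold metrics and
#'   chosen hyperparameters), `summary` (mean +/- SEM of balanced accuracy
#'   and ROC AUC, SEM = SD/sqrt(k_outer)), `scores` (pooled held-out scores,
#'   one row per patient), `coefficient_summary` (mean +/- SD across folds;
#'   linear families), `fold_details` (training patients, standardizer
#'   parameters, chosen hyperparameters per fold), `seed`, `spec`.
#' @export
nested_cv <- function(features, labels, spec = model_spec("l2_logistic"),
                      k_outer = 10L, k_inner = 5L, seed = 1L,
                      pathways = NULL) {
  stopifnot(inherits(features, "feature_matrix"), inherits(spec, "model_spec"))
  if (!is.null(names(labels))) {
    missing_pat <- setdiff(features$patient_ids, names(labels))
    if (length(missing_pat))
      stopf("labels missing for patient(s): %s", paste(missing_pat, collapse = ", "))
    labels <- labels[features$patient_ids]
  }
  labels <- as.character(labels)
  if (length(labels) != length(features$patient_ids))
    stopf("labels must align with the feature matrix's patients")
  bad <- setdiff(unique(labels), c(NEGATIVE_CLASS, POSITIVE_CLASS))
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  class_n <- table(labels)
  if (length(class_n) < 2L || any(class_n < k_outer))
    stopf("stratified %d-fold CV needs >= %d patients per class (have %s)",
          k_outer, k_outer, paste(sprintf("%s=%d", names(class_n), class_n),
                                  collapse = ", "))
  if (spec$family == "pathway_supported" && is.null(pathways))
    stopf("pathway_supported family requires a pathway collection")

  patients <- features$patient_ids
  withr::with_seed(seed, {
    outer_fold <- .stratified_folds(labels, k_outer)
    fold_seeds <- sample.int(.Machine$integer.max - 1L, k_outer)
  })

  per_fold <- vector("list", k_outer)
  fold_details <- vector("list", k_outer)
  score_rows <- vector("list", k_outer)
  coef_rows <- vector("list", k_outer)

  for (f in seq_len(k_outer)) {
    train_pat <- patients[outer_fold != f]
    test_pat <- patients[outer_fold == f]
    y_train <- labels[outer_fold != f]
    y_test <- labels[outer_fold == f]

    withr::with_seed(fold_seeds[f], {
      std <- fit_standardizer(features, train_pat)
      x_all <- apply_standardizer(std, features)
      if (spec$family == "pathway_supported") {
        x_all <- pathway_aggregate(x_all, pathways, spec$min_pathway_genes)
      }
      x_train <- t(x_all$values[, train_pat, drop = FALSE])
      x_test <- t(x_all$values[, test_pat, drop = FALSE])

      sel <- .inner_select(x_train, y_train, spec, k_inner)

      if (spec$family == "random_forest") {
        fit <- .fit_rf(x_train, y_train, sel$hyper$ntree, sel$hyper$max_depth)
        scores <- .predict_rf(fit, x_test)
        coefs <- NULL
      } else {
        lambdas <- sort(spec$hyperparameter_grid$lambda, decreasing = TRUE)
        fit <- .fit_linear(x_train, y_train, lambdas)
        scores <- .predict_linear(fit, x_test, sel$hyper$lambda)[, 1L]
        cf <- stats::coef(fit, s = sel$hyper$lambda)[, 1L]
        coefs <- cf[setdiff(names(cf), c("(Intercept)", ".pad."))]
      }
    })

    per_fold[[f]] <- data.frame(
      fold = f,
      n_test = length(test_pat),
      balanced_accuracy = balanced_accuracy(y_test, threshold_prediction(scores)),
      roc_auc = roc_auc(y_test, scores),
      hyperparameters = paste(names(sel$hyper), unlist(sel$hyper),
                              sep = "=", collapse = ";"))
    fold_details[[f]] <- list(train_patients = train_pat,
                              standardizer = list(mean = std$mean, sd = std$sd,
                                                  dropped = std$dropped),
                              chosen_hyperparameters = sel$hyper,
                              inner_auc = sel$inner_auc)
    score_rows[[f]] <- data.frame(patient_id = test_pat, fold = f,
                                  score = unname(scores), label = y_test,
                                  stringsAsFactors = FALSE)
    if (!is.null(coefs)) coef_rows[[f]] <- coefs
  }

  per_fold <- do.call(rbind, per_fold)
  scores_df <- do.call(rbind, score_rows)
  summary_df <- data.frame(
    metric = c("balanced_accuracy", "roc_auc"),
    mean = c(mean(per_fold$balanced_accuracy), mean(per_fold$roc_auc)),
    sem = c(stats::sd(per_fold$balanced_accuracy),
            stats::sd(per_fold$roc_auc)) / sqrt(k_outer))

  coefficient_summary <- NULL
  if (length(coef_rows) && !is.null(coef_rows[[1L]])) {
    all_feats <- unique(unlist(lapply(coef_rows, names)))
    cm <- matrix(NA_real_, k_outer, length(all_feats),
                 dimnames = list(NULL, all_feats))
    for (f in seq_len(k_outer)) cm[f, names(coef_rows[[f]])] <- coef_rows[[f]]
    coefficient_summary <- summarize_importance(cm)
  }

  structure(list(per_fold = per_fold, summary = summary_df,
                 scores = scores_df,
                 coefficient_summary = coefficient_summary,
                 fold_details = fold_details, k_outer = k_outer,
                 k_inner = k_inner, seed = seed, spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %s, %d-fold outer / %d-fold inner nested CV\n",
              x$spec$family, x$k_outer, x$k_inner))
  cat(sprintf("  balanced accuracy: %.3f +/- %.3f (mean +/- SEM)\n",
              s$mean[s$metric == "balanced_accuracy"],
              s$sem[s$metric == "balanced_accuracy"]))
  cat(sprintf("  ROC AUC:           %.3f +/- %.3f (mean +/- SEM)\n",
              s$mean[s$metric == "roc_auc"], s$sem[s$metric == "roc_auc"]))
  invisible(x)
}
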