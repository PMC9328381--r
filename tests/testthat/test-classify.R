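test_that("balanced accuracy is the mean of per-class recalls", {
  truth <- rep(c("nonresponder", "good"), c(43, 42))
  perfect <- truth
  expect_equal(balanced_accuracy(truth, perfect), 1.0)
  expect_equal(balanced_accuracy(truth, rep("nonresponder", 85)), 0.5)
  # TP=30, FN=13, TN=30, FP=12
  pred <- c(rep("nonresponder", 30), rep("good", 13),
            rep("good", 30), rep("nonresponder", 12))
  expect_equal(balanced_accuracy(truth, pred), (30 / 43 + 30 / 42) / 2)
  expect_error(balanced_accuracy(rep("good", 5), rep("good", 5)), "one class")
})

test_that("ROC AUC equals the normalized Mann-Whitney statistic", {
  truth <- c("nonresponder", "nonresponder", "good", "good")
  expect_equal(roc_auc(truth, c(0.9, 0.4, 0.5, 0.1)), 0.75)  # 3 of 4 pairs
  expect_equal(roc_auc(truth, c(0.9, 0.8, 0.5, 0.1)), 1.0)
  expect_equal(roc_auc(truth, c(0.1, 0.2, 0.5, 0.9)), 0.0)
  # ties score half: one tied pair + one concordant pair
  expect_equal(roc_auc(c("nonresponder", "good", "good"), c(0.5, 0.5, 0.2)), 0.75)
  expect_warning(a <- roc_auc(truth, rep(0.3, 4)), "constant scores")
  expect_equal(a, 0.5)
  # complement property on tie-free scores
  withr::with_seed(5, {
    sc <- rnorm(40)
    tr <- sample(c("good", "nonresponder"), 40, replace = TRUE,
                 prob = c(0.5, 0.5))
  })
  expect_equal(roc_auc(tr, sc) + roc_auc(tr, -sc), 1.0)
})

test_that("ROC AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    for (i in 1:5) {
      n <- 30
      tr <- c(rep("nonresponder", 12), rep("good", 18))
      sc <- rnorm(n) + (tr == "nonresponder") * runif(1, 0, 2)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = tr, predictor = sc, levels = c("good", "nonresponder"),
        direction = "<", quiet = TRUE)))
      expect_equal(roc_auc(tr, sc), ref, tolerance = 1e-12)
    }
  })
})

test_that("threshold prediction sweeps monotonically", {
  sc <- c(0.2, 0.5, 0.7, 0.9)
  expect_true(all(threshold_prediction(sc, 0.1) == "nonresponder"))
  expect_true(all(threshold_prediction(sc, 1.1) == "good"))
  counts <- vapply(seq(0, 1, 0.05), function(t)
    sum(threshold_prediction(sc, t) == "nonresponder"), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the nonresponder-detection curve runs from (0,0) to (1,1) monotonically", {
  withr::with_seed(7, {
    sc <- runif(60)
    tr <- rep(c("nonresponder", "good"), 30)
  })
  cv <- nonresponder_detection_curve(sc, tr)
  expect_equal(cv$detected_nonresponders[1L], 0)
  expect_equal(cv$misclassified_good[1L], 0)
  expect_equal(cv$detected_nonresponders[nrow(cv)], 1)
  expect_equal(cv$misclassified_good[nrow(cv)], 1)
  expect_true(all(diff(cv$detected_nonresponders) >= 0))
  expect_true(all(diff(cv$misclassified_good) >= 0))
  # perfect classifier reaches full detection at zero misclassification
  perf <- nonresponder_detection_curve(c(1, 0.9, 0.2, 0.1),
                                       c("nonresponder", "nonresponder",
                                         "good", "good"))
  expect_true(any(perf$detected_nonresponders == 1 & perf$misclassified_good == 0))
})

test_that("pathway aggregation means standardized member genes", {
  withr::with_seed(8, {
    vals <- matrix(rnorm(6 * 10), 6, 10)
  })
  fm <- feature_matrix(vals, sprintf("g%d", 1:6), sprintf("P%02d", 1:10),
                       "expr_ratio")
  std <- fit_standardizer(fm, fm$patient_ids)
  z <- apply_standardizer(std, fm)
  pws <- list(single = "g3", pair = c("g1", "g2"), absent = c("x1", "x2"))
  agg <- pathway_aggregate(z, pws, min_genes = 1L)
  expect_equal(sort(agg$feature_ids), c("pair", "single"))
  expect_equal(agg$values["single", ], z$values["g3", ])
  expect_equal(agg$values["pair", ], colMeans(z$values[c("g1", "g2"), ]))
  expect_error(pathway_aggregate(z, list(absent = "nope"), 1L), "no pathway")

  # planted group signal concentrates in the covering pathway
  withr::with_seed(9, {
    grp <- rep(c(0, 1), each = 20)
    sig <- matrix(rnorm(5 * 40), 5, 40) + 1.5 * rep(grp, each = 5)
    noise <- matrix(rnorm(15 * 40), 15, 40)
  })
  fm2 <- feature_matrix(rbind(sig, noise), sprintf("g%d", 1:20),
                        sprintf("P%02d", 1:40), "expr_ratio")
  z2 <- apply_standardizer(fit_standardizer(fm2, fm2$patient_ids), fm2)
  agg2 <- pathway_aggregate(z2, list(signal = sprintf("g%d", 1:5),
                                     null1 = sprintf("g%d", 6:10),
                                     null2 = sprintf("g%d", 11:20)), 3L)
  diffs <- abs(rowMeans(agg2$values[, grp == 1]) -
                 rowMeans(agg2$values[, grp == 0]))
  expect_equal(names(which.max(diffs)), "signal")
})

test_that("coefficient summaries report mean and sample SD across folds", {
  cm <- rbind(c(a = 1, b = 0.5), c(a = 3, b = 0.5))
  s <- summarize_importance(cm)
  expect_equal(s$mean[s$feature == "a"], 2)
  expect_equal(s$sd[s$feature == "a"], sqrt(2))
  expect_equal(s$sd[s$feature == "b"], 0)
  expect_equal(s$feature[1L], "a")  # ordered by |mean|
})

test_that("nested CV scores every patient once and is seed-reproducible", {
  withr::with_seed(10, {
    n <- 44
    labels <- rep(c("good", "nonresponder"), each = n / 2)
    sep <- ifelse(labels == "nonresponder", 1, -1) + rnorm(n, 0, 0.01)
    vals <- rbind(sep = sep, noise = rnorm(n))
  })
  fm <- feature_matrix(vals, c("sep", "noise"), sprintf("P%02d", 1:n),
                       "expr_ratio")
  cv <- nested_cv(fm, labels, model_spec("l2_logistic"), k_outer = 10L,
                  k_inner = 5L, seed = 3L)
  # partition property: each patient scored exactly once
  expect_setequal(cv$scores$patient_id, fm$patient_ids)
  expect_equal(nrow(cv$scores), n)
  # perfectly separating feature: every fold AUC 1, SEM 0
  expect_true(all(cv$per_fold$roc_auc == 1))
  expect_equal(cv$summary$mean[cv$summary$metric == "roc_auc"], 1)
  expect_equal(cv$summary$sem[cv$summary$metric == "roc_auc"], 0)
  # SEM definition
  expect_equal(cv$summary$sem[cv$summary$metric == "balanced_accuracy"],
               sd(cv$per_fold$balanced_accuracy) / sqrt(10))
  # determinism
  cv2 <- nested_cv(fm, labels, model_spec("l2_logistic"), seed = 3L)
  expect_identical(cv$scores, cv2$scores)
  expect_identical(cv$coefficient_summary, cv2$coefficient_summary)
  # stratification precondition
  expect_error(nested_cv(fm, c(rep("good", 8), rep("nonresponder", 36)),
                         model_spec("l2_logistic"), k_outer = 10L),
               "stratified")
})

test_that("all three model families run and the linear ones report coefficients", {
  withr::with_seed(11, {
    n <- 40
    labels <- rep(c("good", "nonresponder"), each = n / 2)
    vals <- matrix(rnorm(12 * n), 12, n,
                   dimnames = list(sprintf("g%d", 1:12), NULL))
    vals[1:3, labels == "nonresponder"] <- vals[1:3, labels == "nonresponder"] + 1.5
  })
  fm <- feature_matrix(vals, rownames(vals), sprintf("P%02d", 1:n), "expr_ratio")
  pws <- list(sig = sprintf("g%d", 1:3), other = sprintf("g%d", 4:12))

  cv_l2 <- nested_cv(fm, labels, model_spec("l2_logistic"), k_outer = 5L,
                     k_inner = 3L, seed = 1L)
  expect_s3_class(cv_l2$coefficient_summary, "data.frame")
  expect_true(all(sprintf("g%d", 1:12) %in% cv_l2$coefficient_summary$feature))

  cv_rf <- nested_cv(fm, labels, model_spec("random_forest",
                                            expand.grid(ntree = 100L,
                                                        max_depth = NA_integer_)),
                     k_outer = 5L, k_inner = 3L, seed = 1L)
  expect_null(cv_rf$coefficient_summary)
  expect_equal(nrow(cv_rf$per_fold), 5L)

  cv_pw <- nested_cv(fm, labels, model_spec("pathway_supported"),
                     k_outer = 5L, k_inner = 3L, seed = 1L, pathways = pws)
  expect_setequal(cv_pw$coefficient_summary$feature, c("sig", "other"))
  expect_gt(cv_pw$summary$mean[cv_pw$summary$metric == "roc_auc"], 0.6)
  expect_error(nested_cv(fm, labels, model_spec("pathway_supported"),
                         k_outer = 5L, seed = 1L), "requires a pathway")
})

test_that("no training artifact depends on held-out fold values", {
  withr::with_seed(12, {
    n <- 40
    labels <- rep(c("good", "nonresponder"), each = n / 2)
    vals <- matrix(rnorm(15 * n), 15, n,
                   dimnames = list(sprintf("g%d", 1:15), NULL))
  })
  fm <- feature_matrix(vals, rownames(vals), sprintf("P%02d", 1:n), "expr_ratio")
  cv1 <- nested_cv(fm, labels, model_spec("l2_logistic"), k_outer = 5L,
                   k_inner = 3L, seed = 9L)
  # corrupt the values of fold 1's held-out patients and rerun
  test_pat <- cv1$scores$patient_id[cv1$scores$fold == 1L]
  fm2 <- fm
  fm2$values[, test_pat] <- fm2$values[, test_pat] + 1e6
  cv2 <- suppressWarnings(nested_cv(fm2, labels, model_spec("l2_logistic"),
                                    k_outer = 5L, k_inner = 3L, seed = 9L))
  d1 <- cv1$fold_details[[1L]]
  d2 <- cv2$fold_details[[1L]]
  expect_identical(d1$train_patients, d2$train_patients)
  # checksum comparison of training artifacts
  expect_identical(serialize(d1$standardizer, NULL),
                   serialize(d2$standardizer, NULL))
  expect_identical(d1$chosen_hyperparameters, d2$chosen_hyperparameters)
  expect_identical(d1$inner_auc, d2$inner_auc)
})

test_that("permuted labels give chance-level performance on average", {
  withr::with_seed(13, {
    n <- 40
    vals <- matrix(rnorm(20 * n), 20, n,
                   dimnames = list(sprintf("g%d", 1:20), NULL))
  })
  fm <- feature_matrix(vals, rownames(vals), sprintf("P%02d", 1:n), "expr_ratio")
  aucs <- vapply(1:8, function(s) {
    labels <- withr::with_seed(100 + s,
      sample(rep(c("good", "nonresponder"), each = n / 2)))
    cv <- nested_cv(fm, labels, model_spec("l2_logistic"), k_outer = 5L,
                    k_inner = 3L, seed = s)
    cv$summary$mean[cv$summary$metric == "roc_auc"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})
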