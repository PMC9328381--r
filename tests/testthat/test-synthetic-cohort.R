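test_that("DAS28-CRP formula reproduces hand-computed scores and its floor", {
  expect_equal(compute_das28_crp(0, 0, 0, 0), 0.96)
  # 0.56*sqrt(8) + 0.28*sqrt(5) + 0.36*log(11) + 0.014*44 + 0.96
  expect_equal(compute_das28_crp(8, 5, 10, 44), 4.649261, tolerance = 1e-6)
  # monotone in each argument; (28, 28, crp, 100) maximal for fixed crp
  for (crp in c(0, 5, 50)) {
    top <- compute_das28_crp(28, 28, crp, 100)
    expect_true(all(compute_das28_crp(c(0, 10, 27), 28, crp, 100) <= top))
    expect_true(all(compute_das28_crp(28, c(0, 10, 27), crp, 100) <= top))
    expect_true(all(compute_das28_crp(28, 28, crp, c(0, 50, 99)) <= top))
  }
  expect_error(compute_das28_crp(1, 1, -2, 10), "non-negative")
})

test_that("EULAR grid classifies trajectories and is monotone in improvement", {
  expect_equal(eular_category(4.8, 2.8), "good")     # improvement 2.0, end 2.8
  expect_equal(eular_category(4.0, 3.9), "none")     # improvement 0.1
  expect_equal(eular_category(5.0, 5.0), "none")     # zero improvement
  expect_equal(eular_category(6.0, 4.5), "moderate") # improvement 1.5, end > 3.2
  expect_equal(eular_category(6.5, 5.4), "none")     # improvement 1.1, end > 5.1
  # increasing improvement never moves away from good
  rank_cat <- c(none = 1, moderate = 2, good = 3)
  for (base in c(3.5, 4.8, 6.2)) {
    ends <- seq(base, 0.96, length.out = 25)
    cats <- rank_cat[eular_category(rep(base, 25), ends)]
    expect_true(all(diff(cats) >= 0))
  }
})

test_that("clinical simulator is seeded-deterministic and respects config errors", {
  a <- simulate_clinical(30, 30, seed = 7)
  b <- simulate_clinical(30, 30, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_clinical(30, 30, seed = 8)))
  expect_true(all(a$eular[a$response == "good"] == "good"))
  expect_true(all(a$eular[a$response == "nonresponder"] == "none"))
  expect_true(all(a$swollen28 %in% 0:28))
  expect_true(all(a$crp >= 0))

  bad <- default_clinical_params()
  bad$good$female_prop <- 1.3
  expect_error(simulate_clinical(5, 5, bad, seed = 1), "proportion")
})

test_that("cohort simulator emits the configured design with ground truth", {
  cfg <- simulation_config(n_good = 42L, n_nonresponder = 43L,
                           n_genes = 1000L, seed = 1L,
                           module_spec = list(
                             list(size = 80L, cor = 0.6, group = "both"),
                             list(size = 50L, cor = 0.7, group = "nonresponder_only")))
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$expr_pre$values), c(1000L, 85L))
  expect_equal(dim(co$expr_wk4$values), c(1000L, 85L))
  expect_equal(nrow(co$samples), 170L)
  expect_equal(sum(table(co$clinical$response) == c(42L, 43L)), 2L)
  expect_equal(sum(co$ground_truth$modules != "grey"), 130L)
  expect_equal(length(co$ground_truth$signal_genes), cfg$n_signal_genes)
  # seeded determinism
  expect_identical(co$expr_pre$values, simulate_cohort(cfg)$expr_pre$values)

  expect_error(simulation_config(n_genes = 100L, module_spec = list(
    list(size = 80L, cor = 0.6, group = "both"),
    list(size = 50L, cor = 0.6, group = "both"))), "disjoint")
  expect_error(simulation_config(module_spec = list(
    list(size = 10L, cor = 1.2, group = "both"))), "correlation targets")
})

test_that("planted modules reach their within-module correlation target", {
  cfg <- simulation_config(n_good = 30L, n_nonresponder = 30L, n_genes = 400L,
                           n_signal_genes = 0L, seed = 3L,
                           module_spec = list(
                             list(size = 60L, cor = 0.6, group = "both"),
                             list(size = 40L, cor = 0.8, group = "both")))
  co <- simulate_cohort(cfg)
  gt <- co$ground_truth$modules
  for (m in c("M1", "M2")) {
    genes <- names(gt)[gt == m]
    cm <- cor(t(co$expr_pre$values[genes, ]))
    target <- if (m == "M1") 0.6 else 0.8
    expect_lt(abs(mean(abs(cm[upper.tri(cm)])) - target), 0.1)
  }
  # nonresponder-only module correlates within nonresponders, not within goods
  cfg2 <- simulation_config(n_good = 40L, n_nonresponder = 40L, n_genes = 300L,
                            n_signal_genes = 0L, seed = 4L,
                            module_spec = list(
                              list(size = 50L, cor = 0.7, group = "nonresponder_only")))
  co2 <- simulate_cohort(cfg2)
  genes <- names(co2$ground_truth$modules)[co2$ground_truth$modules == "M1"]
  is_nr <- co2$samples$response[match(co2$expr_pre$sample_ids,
                                      co2$samples$sample_id)] == "nonresponder"
  cm_nr <- cor(t(co2$expr_pre$values[genes, is_nr]))
  cm_good <- cor(t(co2$expr_pre$values[genes, !is_nr]))
  expect_gt(mean(abs(cm_nr[upper.tri(cm_nr)])), 0.55)
  expect_lt(mean(abs(cm_good[upper.tri(cm_good)])), 0.25)
})

test_that("a zero planted signal yields null-calibrated per-gene delta tests", {
  cfg <- simulation_config(n_good = 40L, n_nonresponder = 40L, n_genes = 400L,
                           module_spec = list(), n_signal_genes = 0L, seed = 5L)
  co <- simulate_cohort(cfg)
  pairing <- align_paired_design(co$expr_pre, co$expr_wk4, co$samples)
  dm <- delta_expression(co$expr_pre, co$expr_wk4, pairing)
  resp <- co$clinical$response[match(dm$patient_ids, co$clinical$patient_id)]
  p <- apply(dm$values, 1L, function(v)
    stats::t.test(v[resp == "good"], v[resp == "nonresponder"])$p.value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})
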