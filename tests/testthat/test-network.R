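test_that("gene correlations match the per-pair closed form", {
  withr::with_seed(20, {
    x <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(sprintf("g%d", 1:5), NULL))
  })
  cm <- correlation_matrix(x)
  for (i in 1:5) {
    for (j in 1:5) {
      xi <- x[i, ] - mean(x[i, ])
      xj <- x[j, ] - mean(x[j, ])
      ref <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
      expect_equal(cm[i, j], ref, tolerance = 1e-12)
    }
  }
  # duplicated gene and negated gene
  y <- rbind(a = x[1, ], b = x[1, ], c = -x[1, ])
  cy <- correlation_matrix(y)
  expect_equal(cy["a", "b"], 1)
  expect_equal(cy["a", "c"], -1)
  flat <- rbind(a = x[1, ], z = rep(2, 10))
  expect_error(correlation_matrix(flat), "zero-variance.*z")
})

test_that("soft-threshold adjacency follows |cor|^beta with zero diagonal", {
  cm <- rbind(c(1, -0.5, 0.8), c(-0.5, 1, 0.2), c(0.8, 0.2, 1))
  a2 <- adjacency(cm, 2)
  expect_equal(a2[1, 2], 0.25)
  expect_equal(diag(a2), rep(0, 3))
  expect_equal(unname(adjacency(cm, 1)[1, 3]), 0.8)
  # monotone: larger beta never increases any off-diagonal entry
  a6 <- adjacency(cm, 6)
  expect_true(all(a6[upper.tri(a6)] <= a2[upper.tri(a2)]))
})

test_that("connectivity sums adjacency to all other genes", {
  a <- rbind(c(0, 0.5, 0.2), c(0.5, 0, 0.3), c(0.2, 0.3, 0))
  expect_equal(unname(connectivity(a)), c(0.7, 0.8, 0.5))
  expect_equal(unname(connectivity(matrix(0, 3, 3))), rep(0, 3))
  # permutation-equivariant
  p <- c(3, 1, 2)
  expect_equal(unname(connectivity(a[p, p])), unname(connectivity(a))[p])
})

test_that("topological overlap matches hand-worked and brute-force oracles", {
  # 3 genes, all pairwise adjacency 0.5: TOM = (0.25 + 0.5)/(1 + 1 - 0.5)
  a <- matrix(0.5, 3, 3)
  diag(a) <- 0
  tom <- topological_overlap(a)
  expect_equal(unname(tom[upper.tri(tom)]), rep(0.5, 3))
  expect_equal(diag(tom), rep(1, 3))
  # zero adjacency: off-diagonal TOM all zero
  z <- topological_overlap(matrix(0, 4, 4))
  expect_true(all(z[upper.tri(z)] == 0))
  # random 20x20 vs the triple-loop oracle
  withr::with_seed(21, {
    r <- matrix(runif(400, 0, 0.6), 20, 20)
  })
  r <- (r + t(r)) / 2
  diag(r) <- 0
  expect_lt(max(abs(topological_overlap(r) - tom_oracle(r))), 1e-10)
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("TOM entries stay in [0,1] and vanish with adjacency", {
  withr::with_seed(22, {
    for (i in 1:5) {
      n <- sample(5:25, 1)
      a <- matrix(runif(n * n), n, n)
      a <- (a + t(a)) / 2
      diag(a) <- 0
      tom <- topological_overlap(a)
      expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
      expect_equal(tom, t(tom))
      # zero adjacency row implies zero off-diagonal TOM for that gene
      a[1, ] <- 0
      a[, 1] <- 0
      tom0 <- topological_overlap(a)
      expect_true(all(tom0[1, -1] == 0))
    }
  })
})

test_that("scale-free criterion picks the smallest adequate power", {
  # hub-structured network: few high-variance hub factors, many satellites
  withr::with_seed(23, {
    n_samp <- 50
    hubs <- matrix(rnorm(4 * n_samp), 4, n_samp)
    sat <- do.call(rbind, lapply(1:120, function(i) {
      h <- sample(4, 1)
      w <- runif(1, 0.3, 0.95)
      w * hubs[h, ] + sqrt(1 - w^2) * rnorm(n_samp)
    }))
    x <- rbind(hubs, sat)
    rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  })
  cm <- correlation_matrix(x)
  sf <- soft_threshold(cm, beta_grid = 1:12, r2_target = 0.8)
  expect_s3_class(sf, "scale_free_fit")
  expect_false(sf$fallback)
  expect_gte(sf$fit$r2[sf$fit$beta == sf$beta], 0.8)
  # no smaller beta reaches the target
  smaller <- sf$fit$r2[sf$fit$beta < sf$beta]
  expect_true(all(is.na(smaller) | smaller < 0.8))
  # singleton grid is chosen trivially when adequate
  sf1 <- soft_threshold(cm, beta_grid = sf$beta, r2_target = 0.8)
  expect_equal(sf1$beta, sf$beta)
  # degenerate all-equal correlations fall back with a warning
  flat <- matrix(0.5, 30, 30)
  diag(flat) <- 1
  expect_warning(sfd <- soft_threshold(flat, beta_grid = 1:3), "falling back|failed")
  expect_true(sfd$fallback)
})

test_that("tree cutting recovers two clean planted blocks exactly", {
  p <- plant_expression(100, 30, sizes = c(60, 40), r = 0.9, seed = 24)
  tom <- topological_overlap(adjacency(correlation_matrix(p$x), 6))
  cut <- cluster_and_cut(tom, min_module_size = 30L)
  expect_setequal(unique(cut$assignment), c("M1", "M2"))
  # labels ordered by decreasing size and block membership exact
  expect_equal(sum(cut$assignment == "M1"), 60L)
  expect_true(all(cut$assignment[p$labels == "T1"] == "M1"))
  expect_true(all(cut$assignment[p$labels == "T2"] == "M2"))
  # every non-grey module respects the size floor
  tab <- table(cut$assignment[cut$assignment != "grey"])
  expect_true(all(tab >= 30L))
  expect_error(cluster_and_cut(tom, min_module_size = 200L), "min_module_size")
})

test_that("unstructured expression stays almost entirely grey", {
  grey_frac <- vapply(1:3, function(s) {
    p <- plant_expression(500, 40, sizes = integer(0), seed = 30 + s)
    tom <- topological_overlap(adjacency(correlation_matrix(p$x), 6))
    mean(cluster_and_cut(tom, 30L)$assignment == "grey")
  }, numeric(1))
  expect_true(all(grey_frac >= 0.9))
})

test_that("module overlap P values are exact hypergeometric upper tails", {
  # N=10, two modules of 5 overlapping completely: P = 1/C(10,5)
  genes <- sprintf("g%d", 1:10)
  a <- setNames(rep(c("M1", "grey"), each = 5), genes)
  b <- setNames(rep(c("K1", "grey"), each = 5), genes)
  p <- module_overlap_test(a, b)
  expect_equal(p["M1", "K1"], 1 / choose(10, 5))
  expect_equal(attr(p, "overlap")["M1", "K1"], 5)
  # zero overlap is certain: P = 1
  b2 <- setNames(rep(c("grey", "K1"), each = 5), genes)
  expect_equal(module_overlap_test(a, b2)["M1", "K1"], 1)
  expect_error(module_overlap_test(a, b[1:8]), "universes")
})

test_that("group-specific module detection keys on consensus grey fraction", {
  genes <- sprintf("g%d", 1:100)
  grp <- setNames(rep(c("M1", "M2", "grey"), c(30, 30, 40)), genes)
  # identical assignments: nothing reported
  expect_equal(nrow(detect_group_specific_modules(grp, grp)), 0L)
  # M1 fully grey in consensus, M2 fully preserved
  cons <- setNames(rep(c("grey", "C1", "grey"), c(30, 30, 40)), genes)
  res <- detect_group_specific_modules(grp, cons)
  expect_equal(res$module, "M1")
  expect_equal(res$grey_fraction, 1)
  expect_lt(res$p_grey_overlap, 0.01)
  # threshold semantics: a single non-grey member defeats threshold 1.0...
  cons2 <- cons
  cons2[1] <- "C9"
  res2 <- detect_group_specific_modules(grp, cons2, grey_fraction_threshold = 0.99)
  expect_equal(nrow(res2), 0L)
  # ...but majority-grey still reports at the default threshold
  expect_equal(detect_group_specific_modules(grp, cons2)$module, "M1")
})

test_that("hub selection takes the top 20% by connectivity with stable ties", {
  genes <- sprintf("g%02d", 1:14)
  assign <- setNames(rep(c("M1", "M2"), c(10, 4)), genes)
  k <- setNames(c(10:1, rep(5, 4)), genes)
  hubs <- hub_genes(assign, k, fraction = 0.20)
  expect_equal(hubs$M1, c("g01", "g02"))      # ceil(0.2*10) = 2
  expect_equal(hubs$M2, "g11")                # ceil(0.2*4) = 1; ties -> lexicographic
  expect_equal(hub_genes(assign, k, fraction = 1.0)$M2, c("g11", "g12", "g13", "g14"))
  expect_error(hub_genes(assign, k, fraction = 0), "fraction")
})

test_that("consensus networks expose group-restricted structure", {
  # same module in both groups: consensus equals the single-group picture
  withr::with_seed(25, {
    shared <- plant_expression(150, 40, sizes = c(50), r = 0.8, seed = 25)
    g1 <- shared$x[, 1:20]
    g2 <- shared$x[, 21:40]
  })
  net <- consensus_modules(list(a = g1, b = g2), beta = 6, min_module_size = 30L)
  cons_m <- net$consensus$assignment[shared$labels == "T1"]
  expect_gt(mean(cons_m != "grey"), 0.9)
  # consensus TOM <= each scaled group TOM is implied by pmin construction;
  # check the observable consequence: consensus modules are no larger
  expect_lte(sum(net$consensus$assignment != "grey"),
             min(sum(net$per_group$a$assignment != "grey") + 10,
                 sum(net$per_group$b$assignment != "grey") + 10))
  # module planted in one group only: modular there, grey in consensus
  withr::with_seed(26, {
    only <- plant_expression(150, 20, sizes = c(50), r = 0.8, seed = 26)
    noise <- plant_expression(150, 20, sizes = integer(0), seed = 27)
  })
  net2 <- consensus_modules(list(active = only$x, silent = noise$x), beta = 6,
                            min_module_size = 30L)
  mod_genes <- names(only$labels)[only$labels == "T1"]
  expect_gt(mean(net2$per_group$active$assignment[mod_genes] != "grey"), 0.9)
  expect_gt(mean(net2$consensus$assignment[mod_genes] == "grey"), 0.9)
  res <- detect_group_specific_modules(net2$per_group$active$assignment,
                                       net2$consensus$assignment)
  expect_gte(nrow(res), 1L)
  expect_error(consensus_modules(list(a = g1, b = g2[1:100, ]), beta = 6),
               "gene sets differ")
})
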