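# Shared fixtures: all synthetic, generated in code at test time.

# genes x samples matrix with disjoint planted latent-factor modules; genes
# outside modules are pure noise.  Returns the matrix and the true labels.
plant_expression <- function(n_genes, n_samples, sizes = integer(0), r = 0.6,
                             noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
    lab <- rep("grey", n_genes)
    lambda <- noise_sd * sqrt(r / (1 - r))
    idx <- 0L
    for (m in seq_along(sizes)) {
      rows <- (idx + 1L):(idx + sizes[m])
      idx <- idx + sizes[m]
      x[rows, ] <- x[rows, ] + lambda * rep(stats::rnorm(n_samples), each = length(rows))
      lab[rows] <- sprintf("T%d", m)
    }
    rownames(x) <- sprintf("g%05d", seq_len(n_genes))
    colnames(x) <- sprintf("s%03d", seq_len(n_samples))
    list(x = x, labels = stats::setNames(lab, rownames(x)))
  })
}

# small fully-specified sample table for core-data tests
make_sample_table <- function(n_patients = 4L, drop_wk4_for = character(0)) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  base <- data.frame(
    patient_id = pid,
    response = rep(c("good", "nonresponder"), length.out = n_patients),
    sex = "female", age_at_onset = 55, haq = 1.0, smoking = "never",
    acpa_positive = TRUE, swollen28 = 5L, tender28 = 8L, crp = 10,
    vas_global = 44, stringsAsFactors = FALSE)
  tab <- rbind(
    cbind(sample_id = paste0(pid, "_pre"), timepoint = "pretreatment", base),
    cbind(sample_id = paste0(pid, "_wk4"), timepoint = "week4", base))
  tab <- tab[!(tab$timepoint == "week4" & tab$patient_id %in% drop_wk4_for), ]
  sample_table(tab)
}

# expression matrices matching make_sample_table(): one row per probe
make_paired_matrices <- function(n_patients = 4L, n_probes = 6L, seed = 1,
                                 drop_wk4_for = character(0)) {
  withr::with_seed(seed, {
    pid <- sprintf("P%02d", seq_len(n_patients))
    probes <- sprintf("pr%02d", seq_len(n_probes))
    wk4_pid <- setdiff(pid, drop_wk4_for)
    pre <- expression_matrix(matrix(stats::rnorm(n_probes * n_patients, 8, 1),
                                    n_probes, n_patients),
                             probes, paste0(pid, "_pre"), "log2")
    wk4 <- expression_matrix(matrix(stats::rnorm(n_probes * length(wk4_pid), 8, 1),
                                    n_probes, length(wk4_pid)),
                             probes, paste0(wk4_pid, "_wk4"), "log2")
    list(pre = pre, wk4 = wk4)
  })
}

# brute-force TOM oracle: explicit loops over gene pairs, independent of the
# matrix-product implementation
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# exact upper-tail hypergeometric by enumerating every n-subset of the universe
hyper_upper_oracle <- function(N, m, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= m)  # first m elements are the "marked" genes
  mean(overlaps >= k)
}

adjusted_rand <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}
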