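#' Simulation configuration for a paired-timepoint expression cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate the study design the package targets: 42 good responders
#' and 43 nonresponders, two timepoints (pretreatment, week 4), planted
#' coexpression modules — some restricted to nonresponders — and a planted
#' response-associated shift in the week-4 minus pretreatment expression
#' difference.
#'
#' @param n_good,n_nonresponder Patients per EULAR response group.
#' @param n_genes Number of genes (probes) to simulate.
#' @param module_spec List of planted modules; each element is a list with
#'   `size` (gene count), `cor` (target mean within-module Pearson
#'   correlation, in (0,1)) and `group` (`"both"` or `"nonresponder_only"`;
#'   for the latter the module's latent factor is active only in
#'   nonresponder samples).  Modules are disjoint.
#' @param n_signal_genes Number of genes carrying the planted longitudinal
#'   response signal (drawn from genes outside planted modules).
#' @param signal_effect Standardized mean difference, between response
#'   groups, of the week-4 minus pretreatment log2 difference at signal
#'   genes.  The applied week-4 shift is `signal_effect * sqrt(2) * noise_sd`
#'   so the effect is standardized on the delta scale (delta noise SD is
#'   `sqrt(2) * noise_sd`).
#' @param noise_sd Per-array residual SD in log2 units.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   abundance.
#' @param clinical_params See [default_clinical_params()].
#' @param seed Integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_good = 42L, n_nonresponder = 43L,
                              n_genes = 5000L,
                              module_spec = list(
                                list(size = 150L, cor = 0.6, group = "both"),
                                list(size = 100L, cor = 0.6, group = "both"),
                                list(size = 80L, cor = 0.6, group = "nonresponder_only"),
                                list(size = 60L, cor = 0.6, group = "nonresponder_only")),
                              n_signal_genes = 50L, signal_effect = 1.0,
                              noise_sd = 0.3,
                              baseline_mean = 7.5, baseline_sd = 1.2,
                              clinical_params = default_clinical_params(),
                              seed = 1L) {
  stopifnot(n_good >= 1L, n_nonresponder >= 1L, n_genes >= 1L,
            n_signal_genes >= 0L, noise_sd > 0)
  sizes <- vapply(module_spec, function(m) as.integer(m$size), integer(1))
  cors <- vapply(module_spec, function(m) as.numeric(m$cor), numeric(1))
  grps <- vapply(module_spec, function(m) as.character(m$group), character(1))
  if (any(sizes < 1L)) stopf("module sizes must be positive")
  if (any(cors <= 0 | cors >= 1)) stopf("module correlation targets must lie in (0, 1)")
  bad <- setdiff(grps, c("both", "nonresponder_only"))
  if (length(bad)) stopf("unknown module group restriction: %s", paste(bad, collapse = ", "))
  if (sum(sizes) > n_genes)
    stopf("module sizes sum to %d > n_genes = %d (modules are disjoint)",
          sum(sizes), n_genes)
  if (sum(sizes) + n_signal_genes > n_genes)
    stopf("not enough non-module genes to place %d signal genes", n_signal_genes)
  structure(list(n_good = as.integer(n_good),
                 n_nonresponder = as.integer(n_nonresponder),
                 n_genes = as.integer(n_genes), module_spec = module_spec,
                 n_signal_genes = as.integer(n_signal_genes),
                 signal_effect = signal_effect, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 clinical_params = clinical_params, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a paired two-timepoint expression cohort with planted structure
#'
#' Generates pretreatment and week-4 log2 expression matrices, a sample
#' metadata table and ground truth, under a latent-factor model: each planted
#' module m has one factor per array, and member genes are
#' `baseline + lambda * factor + noise` with
#' `lambda = noise_sd * sqrt(r / (1 - r))`, which makes the expected
#' within-module Pearson correlation equal to the target `r`.  Modules with
#' `group = "nonresponder_only"` have their factor active only in arrays from
#' nonresponders, so they form a coexpression module in the nonresponder
#' network but not in good responders.  Signal genes receive a week-4 mean
#' shift in nonresponders only (alternating sign across genes), giving a
#' standardized between-group delta-expression effect of `signal_effect`.
#' Clinical covariates and EULAR labels come from [simulate_clinical()].
#'
#' @param config A [simulation_config()].
#' @return A list with elements `expr_pre` and `expr_wk4`
#'   ([expression_matrix()], scale `"log2"`), `samples` (a [sample_table()]
#'   with two rows per patient), `clinical` (per-patient frame incl. month-3
#'   covariates and the DAS28 trajectory), and `ground_truth` (named module
#'   label vector with `"grey"` for non-module genes, `module_groups`,
#'   `signal_genes`, `signal_sign`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    clin <- simulate_clinical(cfg$n_good, cfg$n_nonresponder,
                              cfg$clinical_params,
                              seed = derive_seed(cfg$seed, "clinical"))
    n_pat <- nrow(clin)
    is_nr <- clin$response == "nonresponder"

    gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
    sizes <- vapply(cfg$module_spec, function(m) as.integer(m$size), integer(1))
    module_of <- rep("grey", cfg$n_genes)
    idx <- 0L
    for (m in seq_along(sizes)) {
      module_of[(idx + 1L):(idx + sizes[m])] <- sprintf("M%d", m)
      idx <- idx + sizes[m]
    }
    free_genes <- which(module_of == "grey")
    signal_idx <- if (cfg$n_signal_genes > 0L)
      sort(sample(free_genes, cfg$n_signal_genes)) else integer(0)
    signal_sign <- rep_len(c(1, -1), length(signal_idx))

    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

    make_matrix <- function() {
      vals <- baseline +
        matrix(stats::rnorm(cfg$n_genes * n_pat, 0, cfg$noise_sd),
               cfg$n_genes, n_pat)
      idx <- 0L
      for (m in seq_along(cfg$module_spec)) {
        spec <- cfg$module_spec[[m]]
        rows <- (idx + 1L):(idx + sizes[m])
        idx <- idx + sizes[m]
        fac <- stats::rnorm(n_pat)
        if (spec$group == "nonresponder_only") fac[!is_nr] <- 0
        lambda <- cfg$noise_sd * sqrt(spec$cor / (1 - spec$cor))
        vals[rows, ] <- vals[rows, ] + lambda * rep(fac, each = length(rows))
      }
      vals
    }

    pre <- make_matrix()
    wk4 <- make_matrix()
    if (length(signal_idx)) {
      shift <- cfg$signal_effect * sqrt(2) * cfg$noise_sd * signal_sign
      wk4[signal_idx, is_nr] <- wk4[signal_idx, is_nr] + shift
    }

    pre_ids <- paste0(clin$patient_id, "_pre")
    wk4_ids <- paste0(clin$patient_id, "_wk4")
    expr_pre <- expression_matrix(pre, gene_ids, pre_ids, "log2")
    expr_wk4 <- expression_matrix(wk4, gene_ids, wk4_ids, "log2")

    covar_cols <- c("patient_id", "response", "sex", "age_at_onset", "haq",
                    "smoking", "acpa_positive", "swollen28", "tender28",
                    "crp", "vas_global")
    base_cov <- clin[, covar_cols]
    samples <- rbind(
      cbind(sample_id = pre_ids, timepoint = "pretreatment", base_cov),
      cbind(sample_id = wk4_ids, timepoint = "week4", base_cov))
    samples <- samples[order(samples$patient_id, samples$timepoint), ]
    samples <- sample_table(samples)

    names(module_of) <- gene_ids
    ground_truth <- list(
      modules = module_of,
      module_groups = vapply(cfg$module_spec, function(m) m$group, character(1)),
      signal_genes = gene_ids[signal_idx],
      signal_sign = stats::setNames(signal_sign, gene_ids[signal_idx]))

    list(expr_pre = expr_pre, expr_wk4 = expr_wk4, samples = samples,
         clinical = clin, ground_truth = ground_truth, config = cfg)
  })
}
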