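#' Pipeline configuration
#'
#' Validates every stage's parameters up front so a misconfigured run fails
#' before any stage executes.  One global `seed` deterministically derives
#' per-stage seeds.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param simulation A [simulation_config()], or `NULL` to supply data via
#'   the `data` argument of [run_pipeline()].
#' @param contrast Feature set for classification: `expr_ratio` (default),
#'   `expr_pre`, `expr_wk4`, `clinical_baseline` or `clinical_3mo`.
#' @param model A [model_spec()].
#' @param k_outer,k_inner Nested CV fold counts.
#' @param floor,z_cutoff Preprocessing: expression floor (raw scale) and PCA
#'   outlier z cutoff.
#' @param network_timepoint Which timepoint's samples feed the network stage.
#' @param beta Soft-threshold power; `NULL` selects by the scale-free
#'   criterion on the nonresponder network.
#' @param beta_grid,r2_target,min_module_size,hub_fraction,grey_fraction_threshold
#'   Network stage parameters (see [coexpression_network()],
#'   [detect_group_specific_modules()], [hub_genes()]).
#' @param pathways Named list term -> genes (or a GMT path) for the
#'   enrichment stage and the `pathway_supported` family; `NULL` skips
#'   enrichment.
#' @param evidence_pairs Optional two-column data frame of prior
#'   coexpression evidence pairs.
#' @param min_set_size,max_set_size Gene-set size filter for enrichment.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = simulation_config(),
                            contrast = c("expr_ratio", "expr_pre", "expr_wk4",
                                         "clinical_baseline", "clinical_3mo"),
                            model = model_spec("l2_logistic"),
                            k_outer = 10L, k_inner = 5L,
                            floor = 0, z_cutoff = 4,
                            network_timepoint = c("pretreatment", "week4"),
                            beta = 6, beta_grid = 1:20, r2_target = 0.85,
                            min_module_size = 30L, hub_fraction = 0.20,
                            grey_fraction_threshold = 0.5,
                            pathways = NULL, evidence_pairs = NULL,
                            min_set_size = 10L, max_set_size = 2000L,
                            seed = 1L) {
  contrast <- match.arg(contrast)
  network_timepoint <- match.arg(network_timepoint)
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  stopifnot(inherits(model, "model_spec"))
  assert_scalar_number(k_outer, "k_outer", lower = 2)
  assert_scalar_number(k_inner, "k_inner", lower = 2)
  if (is.character(pathways) && length(pathways) == 1L)
    pathways <- read_gmt(pathways)
  structure(list(out_dir = out_dir, simulation = simulation,
                 contrast = contrast, model = model,
                 k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 floor = floor, z_cutoff = z_cutoff,
                 network_timepoint = network_timepoint, beta = beta,
                 beta_grid = beta_grid, r2_target = r2_target,
                 min_module_size = as.integer(min_module_size),
                 hub_fraction = hub_fraction,
                 grey_fraction_threshold = grey_fraction_threshold,
                 pathways = pathways, evidence_pairs = evidence_pairs,
                 min_set_size = min_set_size, max_set_size = max_set_size,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (optional), preprocess, features,
#' classify, network, enrich — writing each stage's artifacts under
#' `config$out_dir` together with a JSON manifest recording the package
#' version, seeds, parameters and per-file MD5 checksums.  Reruns with the
#' same configuration and seed produce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param data Optional pre-loaded input list with elements `expr_pre`,
#'   `expr_wk4`, `samples` (and optionally `clinical`); used when
#'   `config$simulation` is `NULL`.
#' @param verbose Emit one log line per stage event (default TRUE).
#' @return A list with the in-memory stage results: `cohort`, `qc`,
#'   `features`, `cv`, `curve`, `network`, `group_specific`, `hubs`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, data = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # -- simulate ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- derive_seed(seed, "simulate")
    cohort <- simulate_cohort(sim_cfg)
    .stage_log(verbose, "simulate", "%d genes x %d patients (%d good, %d nonresponder)",
               sim_cfg$n_genes, nrow(cohort$clinical),
               sum(cohort$clinical$response == "good"),
               sum(cohort$clinical$response == "nonresponder"))
  } else {
    if (is.null(data)) stopf("no simulation config and no data supplied")
    cohort <- data
  }

  # -- preprocess -------------------------------------------------------------
  to_raw <- function(em) expression_matrix(2^em$values, em$probe_ids,
                                           em$sample_ids, "raw")
  pp_pre <- preprocess_expression(to_raw(cohort$expr_pre), floor = config$floor,
                                  z_cutoff = config$z_cutoff)
  pp_wk4 <- preprocess_expression(to_raw(cohort$expr_wk4), floor = config$floor,
                                  z_cutoff = config$z_cutoff)
  shared <- intersect(pp_pre$matrix$probe_ids, pp_wk4$matrix$probe_ids)
  keep <- function(em) expression_matrix(em$values[shared, , drop = FALSE],
                                         shared, em$sample_ids, em$scale_tag)
  expr_pre <- keep(pp_pre$matrix)
  expr_wk4 <- keep(pp_wk4$matrix)
  .stage_log(verbose, "preprocess",
             "probes: %d -> %d (pre), %d -> %d (wk4); outliers: %s",
             pp_pre$report$n_probes_in, pp_pre$report$n_probes_out,
             pp_wk4$report$n_probes_in, pp_wk4$report$n_probes_out,
             paste(c(pp_pre$report$outlier_samples,
                     pp_wk4$report$outlier_samples, "none")[1L], collapse = ","))

  # -- features ---------------------------------------------------------------
  pairing <- align_paired_design(expr_pre, expr_wk4, cohort$samples)
  feats <- switch(config$contrast,
    expr_ratio = as_feature_matrix(delta_expression(expr_pre, expr_wk4, pairing)),
    expr_pre = timepoint_features(expr_pre, pairing, "pretreatment"),
    expr_wk4 = timepoint_features(expr_wk4, pairing, "week4"),
    clinical_baseline = encode_clinical(cohort$clinical %||% cohort$samples,
                                        "clinical_baseline"),
    clinical_3mo = encode_clinical(cohort$clinical, "clinical_3mo"))
  if (config$contrast %in% c("clinical_baseline", "clinical_3mo")) {
    fkeep <- intersect(feats$patient_ids, pairing$patient_id)
    feats <- feature_matrix(feats$values[, fkeep, drop = FALSE],
                            feats$feature_ids, fkeep, feats$contrast_tag)
  }
  .stage_log(verbose, "features", "%s: %d features x %d patients",
             config$contrast, nrow(feats$values), ncol(feats$values))

  # -- classify ---------------------------------------------------------------
  labels <- stats::setNames(as.character(cohort$samples$response),
                            cohort$samples$patient_id)
  labels <- labels[!duplicated(names(labels))]
  cv <- nested_cv(feats, labels[feats$patient_ids], spec = config$model,
                  k_outer = config$k_outer, k_inner = config$k_inner,
                  seed = derive_seed(seed, "classify"),
                  pathways = config$pathways)
  curve <- nonresponder_detection_curve(cv$scores$score, cv$scores$label)
  .stage_log(verbose, "classify", "AUC %.3f +/- %.3f; balanced accuracy %.3f +/- %.3f",
             cv$summary$mean[2L], cv$summary$sem[2L],
             cv$summary$mean[1L], cv$summary$sem[1L])

  # -- network ----------------------------------------------------------------
  net_expr <- if (config$network_timepoint == "pretreatment") expr_pre else expr_wk4
  sm <- cohort$samples[match(net_expr$sample_ids, cohort$samples$sample_id), ]
  split_cols <- split(seq_len(ncol(net_expr$values)), as.character(sm$response))
  # quantile normalization can leave rank-stable genes constant within a
  # group; correlations are undefined there, so drop them up front
  flat <- Reduce(`|`, lapply(split_cols, function(j)
    apply(net_expr$values[, j, drop = FALSE], 1L, stats::sd) == 0))
  if (any(flat)) {
    warnf("excluding %d zero-variance gene(s) from the network stage", sum(flat))
    net_expr <- expression_matrix(net_expr$values[!flat, , drop = FALSE],
                                  net_expr$probe_ids[!flat],
                                  net_expr$sample_ids, net_expr$scale_tag)
  }
  beta <- config$beta
  if (is.null(beta)) {
    sf <- soft_threshold(correlation_matrix(
      net_expr$values[, split_cols$nonresponder, drop = FALSE]),
      beta_grid = config$beta_grid, r2_target = config$r2_target)
    beta <- sf$beta
  }
  net <- consensus_modules(
    lapply(split_cols, function(j) net_expr$values[, j, drop = FALSE]),
    beta = beta, min_module_size = config$min_module_size)
  group_specific <- detect_group_specific_modules(
    net$per_group$nonresponder$assignment, net$consensus$assignment,
    config$grey_fraction_threshold)
  hubs <- if (any(net$per_group$nonresponder$assignment != "grey"))
    hub_genes(net$per_group$nonresponder$assignment,
              net$per_group_connectivity$nonresponder, config$hub_fraction)
    else list()
  .stage_log(verbose, "network", "beta=%s; %d nonresponder module(s), %d group-specific",
             format(beta),
             length(setdiff(unique(net$per_group$nonresponder$assignment), "grey")),
             nrow(group_specific))

  # -- enrich -----------------------------------------------------------------
  enrichment <- NULL
  evidence <- NULL
  if (!is.null(config$pathways) && nrow(group_specific)) {
    universe <- shared
    sets <- restrict_gene_sets(config$pathways, universe,
                               config$min_set_size, config$max_set_size)
    if (length(sets)) {
      enrichment <- lapply(group_specific$module, function(m) {
        q <- hubs[[m]] %||% names(net$per_group$nonresponder$assignment)[
          net$per_group$nonresponder$assignment == m]
        hypergeometric_enrichment(q, sets, universe)
      })
      names(enrichment) <- group_specific$module
    }
    if (!is.null(config$evidence_pairs) && length(hubs))
      evidence <- prior_coexpression_fraction(hubs[group_specific$module],
                                              config$evidence_pairs)
    .stage_log(verbose, "enrich", "%d gene set(s) tested over %d module(s)",
               length(sets), length(enrichment %||% list()))
  }

  # -- write artifacts --------------------------------------------------------
  paths <- character(0)
  wr <- function(obj, file, writer) {
    p <- file.path(config$out_dir, file)
    writer(obj, p)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  wr_tsv <- function(obj, p) utils::write.table(obj, p, sep = "\t",
                                                quote = FALSE, row.names = FALSE)
  wr(cohort$samples, "samples.tsv", write_sample_table)
  wr(cv$per_fold, "cv_folds.tsv", wr_tsv)
  wr(cv$scores, "cv_scores.tsv", wr_tsv)
  wr(curve, "detection_curve.tsv", wr_tsv)
  if (!is.null(cv$coefficient_summary))
    wr(utils::head(cv$coefficient_summary, 100L), "top_coefficients.tsv", wr_tsv)
  nr_assign <- net$per_group$nonresponder$assignment
  module_table <- data.frame(
    gene = names(nr_assign), module = unname(nr_assign),
    consensus_module = unname(net$consensus$assignment[names(nr_assign)]),
    connectivity = unname(net$per_group_connectivity$nonresponder[names(nr_assign)]),
    is_hub = names(nr_assign) %in% unlist(hubs))
  wr(module_table, "modules.tsv", wr_tsv)
  wr(group_specific, "group_specific_modules.tsv", wr_tsv)
  if (!is.null(enrichment))
    wr(do.call(rbind, Map(cbind, module = names(enrichment), enrichment)),
       "enrichment.tsv", wr_tsv)

  manifest <- list(
    package = "mtxresponse",
    version = as.character(utils::packageVersion("mtxresponse")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                       classify = derive_seed(seed, "classify")),
    contrast = config$contrast, family = config$model$family,
    k_outer = config$k_outer, k_inner = config$k_inner,
    beta = beta, min_module_size = config$min_module_size,
    summary = list(
      roc_auc_mean = cv$summary$mean[2L], roc_auc_sem = cv$summary$sem[2L],
      balanced_accuracy_mean = cv$summary$mean[1L],
      balanced_accuracy_sem = cv$summary$sem[1L],
      n_group_specific_modules = nrow(group_specific)),
    checksums = as.list(tools::md5sum(unlist(paths))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .stage_log(verbose, "manifest", "wrote %d artifact(s) to %s",
             length(paths) + 1L, config$out_dir)

  list(cohort = cohort, qc = list(pre = pp_pre$report, wk4 = pp_wk4$report),
       features = feats, cv = cv, curve = curve, network = net,
       group_specific = group_specific, hubs = hubs,
       enrichment = enrichment, evidence = evidence, manifest = manifest)
}
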