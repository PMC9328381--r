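#' Gene-gene Pearson correlation matrix
#'
#' Correlations between all gene pairs across samples.  Zero-variance genes
#' make the coefficient undefined and must be removed first; they are
#' reported by name.
#'
#' @param expr An [expression_matrix()] / [feature_matrix()] (genes x
#'   samples) or a plain numeric matrix with rownames.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  x <- if (inherits(expr, c("expression_matrix", "feature_matrix"))) expr$values else as.matrix(expr)
  if (ncol(x) < 3L) stopf("need >= 3 samples to estimate correlations")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance gene(s) present: %s",
          paste(utils::head(rownames(x)[sds == 0] %||% which(sds == 0), 5L),
                collapse = ", "))
  stats::cor(t(x))
}

#' Soft-thresholded adjacency
#'
#' `a_ij = |cor_ij|^beta` for `i != j`; the diagonal is fixed at 0 so that
#' connectivity sums run over *other* genes only.
#'
#' @param cor_matrix Symmetric correlation matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix in \[0,1\] with attribute `beta`.
#' @export
adjacency <- function(cor_matrix, beta) {
  assert_scalar_number(beta, "beta", lower = 1)
  a <- abs(cor_matrix)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Whole-network connectivity
#'
#' Per-gene connectivity `k_i = sum_{j != i} a_ij` (the adjacency diagonal is
#' zero by construction).
#'
#' @param adj Adjacency matrix from [adjacency()].
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  rowSums(adj)
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, builds the adjacency, computes the connectivity
#' distribution, bins connectivity into `n_bins` equal-width bins, and
#' regresses `log10 p(k)` on `log10 mean(k)` per bin.  The model fit R^2
#' measures how well the network approximates scale-free topology.  The
#' smallest power reaching `r2_target` is chosen; if none does, the power
#' with maximal R^2 is returned with `fallback = TRUE` and a warning.
#'
#' @param cor_matrix Symmetric gene correlation matrix.
#' @param beta_grid Ascending integer candidate powers.
#' @param r2_target Scale-free fit target (default 0.85).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return An object of class `scale_free_fit`: data frame `fit` (beta, r2,
#'   slope, mean_k, n_bins_used, note), `beta` (chosen power), `fallback`.
#' @export
soft_threshold <- function(cor_matrix, beta_grid = 1:20, r2_target = 0.85,
                           n_bins = 10L) {
  if (!length(beta_grid) || is.unsorted(beta_grid))
    stopf("beta_grid must be non-empty and ascending")
  rows <- lapply(beta_grid, function(beta) {
    k <- connectivity(adjacency(cor_matrix, beta))
    res <- data.frame(beta = beta, r2 = NA_real_, slope = NA_real_,
                      mean_k = mean(k), n_bins_used = NA_integer_,
                      note = "", stringsAsFactors = FALSE)
    if (diff(range(k)) <= 0) {
      res$note <- "degenerate connectivity (all equal)"
      return(res)
    }
    bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
    p_k <- tapply(k, bin, length) / length(k)
    k_mean <- tapply(k, bin, mean)
    keep <- !is.na(p_k) & p_k > 0 & !is.na(k_mean) & k_mean > 0
    if (sum(keep) < 3L) {
      res$note <- "fewer than 3 non-empty bins"
      return(res)
    }
    fit <- stats::lm(log10(p_k[keep]) ~ log10(k_mean[keep]))
    res$r2 <- summary(fit)$r.squared
    res$slope <- unname(stats::coef(fit)[2L])
    res$n_bins_used <- sum(keep)
    res
  })
  fit <- do.call(rbind, rows)
  ok <- which(!is.na(fit$r2) & fit$r2 >= r2_target)
  fallback <- !length(ok)
  if (!fallback) {
    beta <- fit$beta[ok[1L]]
  } else if (any(!is.na(fit$r2))) {
    beta <- fit$beta[which.max(fit$r2)]
    warnf("no power reached scale-free R^2 >= %.2f; falling back to beta = %d (R^2 = %.3f)",
          r2_target, beta, max(fit$r2, na.rm = TRUE))
  } else {
    beta <- fit$beta[1L]
    warnf("scale-free fit failed for every candidate power; using beta = %d", beta)
  }
  structure(list(fit = fit, beta = beta, fallback = fallback,
                 r2_target = r2_target),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit> chosen beta = %d%s (target R^2 = %.2f)\n",
              x$beta, if (x$fallback) " [fallback: max R^2]" else "", x$r2_target))
  print(x$fit[, c("beta", "r2", "slope", "mean_k")], row.names = FALSE)
  invisible(x)
}

#' Topological overlap matrix (unsigned)
#'
#' Similarity of two genes accounting for their shared neighbors:
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with `TOM_ii = 1`.  Genes that are strongly connected to the same
#' neighborhood get high overlap even beyond their direct adjacency.
#'
#' @param adj Adjacency matrix from [adjacency()] (zero diagonal).
#' @return Symmetric TOM with entries in \[0,1\] and unit diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- unclass(adj)
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-12)))
    stopf("adjacency must be symmetric")
  if (any(diag(a) != 0)) stopf("adjacency diagonal must be zero")
  k <- rowSums(a)
  shared <- crossprod(a)           # sum_u a_iu a_uj (diag(a)=0 => u != i, j)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# ---- dynamic tree cut -------------------------------------------------------

# Per-node bookkeeping for an hclust tree: sizes and leaf membership.
.tree_members <- function(hc) {
  n <- nrow(hc$merge) + 1L
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    ch <- hc$merge[i, ]
    members[[i]] <- c(if (ch[1L] < 0) -ch[1L] else members[[ch[1L]]],
                      if (ch[2L] < 0) -ch[2L] else members[[ch[2L]]])
  }
  members
}

#' Detect modules by adaptive tree cutting of a TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a dynamic (adaptive, dendrogram-based) branch decomposition:
#' walking from the root, a branch is declared a module when (i) it has at
#' least `min_module_size` genes, (ii) it completes below the height ceiling
#' (the `cut_height_quantile` quantile of all merge heights), and (iii) it is
#' separated from the rest of the tree by a merge-height gap of at least
#' `min_gap_frac` of the dendrogram height range.  Branches failing the
#' criteria are decomposed further; leaves not captured by any qualifying
#' branch stay unassigned (`"grey"`).  The separation criterion is what keeps
#' unstructured data grey: in a noise dendrogram the late merges concentrate,
#' so no branch is gapped away from the background.
#'
#' @param tom Topological overlap matrix (or any similarity in \[0,1\]).
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height_quantile Height ceiling quantile (default 0.99).
#' @param min_gap_frac Minimum branch separation, as a fraction of the merge
#'   height range (default 0.02).
#' @return A list with `assignment` (named character vector; `"M1"`, `"M2"`,
#'   ... by decreasing size, `"grey"` for unassigned), `dendrogram` (the
#'   `hclust`), and `params`.
#' @export
cluster_and_cut <- function(tom, min_module_size = 30L,
                            cut_height_quantile = 0.99, min_gap_frac = 0.02) {
  n <- nrow(tom)
  if (min_module_size > n)
    stopf("min_module_size (%d) exceeds the number of genes (%d)",
          min_module_size, n)
  gene_ids <- rownames(tom) %||% sprintf("g%d", seq_len(n))
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  hc$labels <- gene_ids

  heights <- hc$height
  h_range <- diff(range(heights))
  cut_height <- stats::quantile(heights, cut_height_quantile, names = FALSE)
  gap_needed <- min_gap_frac * h_range
  members <- .tree_members(hc)
  sizes <- lengths(members)

  labels <- rep("grey", n)
  module_leaves <- list()
  if (h_range > 0) {
    # iterative top-down walk (explicit stack: noise dendrograms can be deep)
    stack_node <- c(nrow(hc$merge))
    stack_parent_h <- c(Inf)
    while (length(stack_node)) {
      node <- stack_node[length(stack_node)]
      parent_h <- stack_parent_h[length(stack_parent_h)]
      stack_node <- stack_node[-length(stack_node)]
      stack_parent_h <- stack_parent_h[-length(stack_parent_h)]
      if (node < 0) next  # single leaf: can never reach min_module_size
      h <- heights[node]
      if (sizes[node] >= min_module_size && h <= cut_height &&
          (parent_h - h) >= gap_needed) {
        module_leaves[[length(module_leaves) + 1L]] <- members[[node]]
      } else {
        ch <- hc$merge[node, ]
        stack_node <- c(stack_node, ch[1L], ch[2L])
        stack_parent_h <- c(stack_parent_h, h, h)
      }
    }
  }
  if (length(module_leaves)) {
    ord <- order(-lengths(module_leaves))
    for (i in seq_along(ord))
      labels[module_leaves[[ord[i]]]] <- sprintf("M%d", i)
  }
  names(labels) <- gene_ids
  list(assignment = labels, dendrogram = hc,
       params = list(min_module_size = min_module_size,
                     cut_height_quantile = cut_height_quantile,
                     min_gap_frac = min_gap_frac, cut_height = cut_height))
}

# ---- consensus and group comparison ----------------------------------------

# Quantile-match a TOM to a reference 95th percentile via a power transform,
# which preserves [0,1] and monotonicity (multiplicative scaling would not).
.scale_tom <- function(tom, q_ref, prob = 0.95) {
  q <- stats::quantile(tom[upper.tri(tom)], prob, names = FALSE)
  if (q <= 0 || q >= 1 || q_ref <= 0 || q_ref >= 1) return(tom)
  out <- tom^(log(q_ref) / log(q))
  diag(out) <- 1
  out
}

#' Consensus and per-group coexpression modules
#'
#' Builds one weighted network per response group over a shared gene set and
#' compares them.  With `approach = "per_group_min"` (default), the per-group
#' TOMs are quantile-scaled to a common 95th percentile and the consensus TOM
#' is their elementwise minimum — a gene pair is only as coexpressed in
#' consensus as it is in its least-coexpressed group.  With
#' `approach = "pooled"`, the consensus network is built on the pooled
#' samples of both groups.  Modules are then detected in the consensus and in
#' each group's own network with [cluster_and_cut()].
#'
#' @param expr_by_group Named list of two genes x samples matrices (or
#'   [expression_matrix()] objects), e.g. `list(good = ..., nonresponder = ...)`.
#' @param beta Soft-threshold power applied to every network.
#' @param min_module_size,cut_height_quantile,min_gap_frac Passed to
#'   [cluster_and_cut()].
#' @param approach `"per_group_min"` or `"pooled"`.
#' @return A list with `consensus` (module assignment list), `per_group`
#'   (named list of assignment lists), `beta`, `approach`.
#' @export
consensus_modules <- function(expr_by_group, beta = 6,
                              min_module_size = 30L,
                              cut_height_quantile = 0.99, min_gap_frac = 0.02,
                              approach = c("per_group_min", "pooled")) {
  approach <- match.arg(approach)
  mats <- lapply(expr_by_group, function(e)
    if (inherits(e, c("expression_matrix", "feature_matrix"))) e$values else as.matrix(e))
  if (length(mats) < 2L) stopf("need at least two groups")
  genes <- rownames(mats[[1L]])
  for (m in mats) {
    if (!identical(sort(rownames(m)), sort(genes)))
      stopf("gene sets differ between groups")
    if (ncol(m) < 3L) stopf("every group needs >= 3 samples")
  }
  mats <- lapply(mats, function(m) m[genes, , drop = FALSE])

  adjs <- lapply(mats, function(m) adjacency(correlation_matrix(m), beta))
  ks <- lapply(adjs, connectivity)
  toms <- lapply(adjs, topological_overlap)

  if (approach == "pooled") {
    pooled <- do.call(cbind, mats)
    cons_tom <- topological_overlap(adjacency(correlation_matrix(pooled), beta))
  } else {
    # reference = smallest group quantile, so scaling only ever shrinks a
    # TOM toward the weakest group's level and can never inflate an
    # unstructured group's background into apparent consensus
    q_ref <- min(vapply(toms, function(tm)
      stats::quantile(tm[upper.tri(tm)], 0.95, names = FALSE), numeric(1)))
    scaled <- lapply(toms, .scale_tom, q_ref = q_ref)
    cons_tom <- Reduce(pmin, scaled)
  }

  cut_one <- function(tm) cluster_and_cut(tm, min_module_size,
                                          cut_height_quantile, min_gap_frac)
  list(consensus = cut_one(cons_tom),
       per_group = lapply(toms, cut_one),
       per_group_connectivity = ks,
       beta = beta, approach = approach)
}

#' Hypergeometric overlap test between two module assignments
#'
#' For every pair of modules (one from each assignment) over the same gene
#' universe of size `N`, computes the upper-tail hypergeometric probability
#' `P(X >= k)` of observing at least the actual overlap `k` when a module of
#' size `m` and one of size `n` are drawn independently.
#'
#' @param assign_a,assign_b Named module label vectors over the same genes.
#' @param include_grey Whether `"grey"` (unassigned) counts as a module
#'   (default FALSE).
#' @return A matrix of P values (rows: modules of `assign_a`; columns:
#'   modules of `assign_b`) with attribute `overlap` (the count matrix).
#' @export
module_overlap_test <- function(assign_a, assign_b, include_grey = FALSE) {
  if (!setequal(names(assign_a), names(assign_b)))
    stopf("module assignments cover different gene universes")
  assign_b <- assign_b[names(assign_a)]
  keep_mods <- function(x) {
    mods <- sort(unique(x))
    if (!include_grey) mods <- setdiff(mods, "grey")
    mods
  }
  mods_a <- keep_mods(assign_a)
  mods_b <- keep_mods(assign_b)
  if (!length(mods_a) || !length(mods_b))
    stopf("no modules to compare (only grey present)")
  N <- length(assign_a)
  p <- matrix(NA_real_, length(mods_a), length(mods_b),
              dimnames = list(mods_a, mods_b))
  ov <- p
  for (i in seq_along(mods_a)) {
    in_a <- assign_a == mods_a[i]
    m <- sum(in_a)
    for (j in seq_along(mods_b)) {
      in_b <- assign_b == mods_b[j]
      n <- sum(in_b)
      k <- sum(in_a & in_b)
      ov[i, j] <- k
      p[i, j] <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    }
  }
  attr(p, "overlap") <- ov
  p
}

#' Modules present in one group but unassigned in consensus
#'
#' Reports each non-grey module of a group-specific network whose members
#' are mostly `"grey"` (unassigned) in the consensus assignment — the
#' signature of group-restricted coexpression.  Each reported module carries
#' its grey fraction and the hypergeometric P value for over-representation
#' of its genes among the consensus grey set.
#'
#' @param group_assign,consensus_assign Named module label vectors over the
#'   same gene universe.
#' @param grey_fraction_threshold Minimum consensus-grey fraction for a
#'   module to be reported (strictly greater than; default 0.5).
#' @return A data frame with columns `module`, `size`, `n_grey_in_consensus`,
#'   `grey_fraction`, `p_grey_overlap`, sorted by decreasing grey fraction.
#' @export
detect_group_specific_modules <- function(group_assign, consensus_assign,
                                          grey_fraction_threshold = 0.5) {
  if (!setequal(names(group_assign), names(consensus_assign)))
    stopf("assignments cover different gene universes")
  consensus_assign <- consensus_assign[names(group_assign)]
  N <- length(group_assign)
  grey_cons <- consensus_assign == "grey"
  mods <- setdiff(sort(unique(group_assign)), "grey")
  rows <- lapply(mods, function(m) {
    in_m <- group_assign == m
    k <- sum(in_m & grey_cons)
    data.frame(module = m, size = sum(in_m), n_grey_in_consensus = k,
               grey_fraction = k / sum(in_m),
               p_grey_overlap = stats::phyper(k - 1, sum(grey_cons),
                                              N - sum(grey_cons), sum(in_m),
                                              lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(module = character(0), size = integer(0),
               n_grey_in_consensus = integer(0), grey_fraction = numeric(0),
               p_grey_overlap = numeric(0))
  out <- out[out$grey_fraction > grey_fraction_threshold, , drop = FALSE]
  out[order(-out$grey_fraction, out$module), , drop = FALSE]
}

#' Hub genes by within-module connectivity
#'
#' Ranks genes within each (non-grey) module by whole-network connectivity
#' and keeps the top `fraction` (ceiling), on the rationale that only a
#' fraction of module members drive the module's main biological function.
#' Ties are broken lexicographically by gene identifier for determinism.
#'
#' @param assign Named module label vector.
#' @param k Named connectivity vector from [connectivity()].
#' @param fraction Fraction of genes kept per module (default 0.20).
#' @return Named list: module -> character vector of hub gene IDs.
#' @export
hub_genes <- function(assign, k, fraction = 0.20) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  missing_k <- setdiff(names(assign), names(k))
  if (length(missing_k)) stopf("connectivity missing for some genes")
  mods <- setdiff(sort(unique(assign)), "grey")
  out <- lapply(mods, function(m) {
    genes <- names(assign)[assign == m]
    genes <- genes[order(-k[genes], genes)]
    genes[seq_len(ceiling(fraction * length(genes)))]
  })
  stats::setNames(out, mods)
}

#' Single-network coexpression analysis
#'
#' End-to-end weighted coexpression analysis of one expression matrix:
#' Pearson correlation, soft-threshold selection by the scale-free topology
#' criterion (unless `beta` is given), adjacency, topological overlap,
#' module detection by adaptive tree cutting, connectivity, and top-20%
#' hub genes per module.
#'
#' @param expr Genes x samples matrix or [expression_matrix()].
#' @param beta Soft-threshold power; `NULL` to select via [soft_threshold()].
#' @param beta_grid,r2_target Passed to [soft_threshold()].
#' @param min_module_size,cut_height_quantile,min_gap_frac Passed to
#'   [cluster_and_cut()].
#' @param hub_fraction Passed to [hub_genes()].
#' @param keep_matrices Keep the adjacency and TOM in the result (memory
#'   heavy for large gene sets; default FALSE).
#' @return An object of class `coexpression_result` with `beta`,
#'   `scale_free_fit` (or NULL), `modules` (assignment), `dendrogram`,
#'   `connectivity`, `hubs`, and optionally `adjacency`, `tom`.
#' @export
coexpression_network <- function(expr, beta = NULL, beta_grid = 1:20,
                                 r2_target = 0.85, min_module_size = 30L,
                                 cut_height_quantile = 0.99,
                                 min_gap_frac = 0.02, hub_fraction = 0.20,
                                 keep_matrices = FALSE) {
  cm <- correlation_matrix(expr)
  sf <- NULL
  if (is.null(beta)) {
    sf <- soft_threshold(cm, beta_grid = beta_grid, r2_target = r2_target)
    beta <- sf$beta
  }
  adj <- adjacency(cm, beta)
  k <- connectivity(adj)
  tom <- topological_overlap(adj)
  cut <- cluster_and_cut(tom, min_module_size, cut_height_quantile,
                         min_gap_frac)
  hubs <- if (any(cut$assignment != "grey"))
    hub_genes(cut$assignment, k, hub_fraction) else list()
  out <- list(beta = beta, scale_free_fit = sf, modules = cut$assignment,
              dendrogram = cut$dendrogram, connectivity = k, hubs = hubs,
              params = cut$params)
  if (keep_matrices) {
    out$adjacency <- adj
    out$tom <- tom
  }
  structure(out, class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  tab <- table(x$modules)
  n_mod <- sum(names(tab) != "grey")
  cat(sprintf("<coexpression_result> beta = %s; %d module(s); %d/%d genes grey\n",
              format(x$beta), n_mod,
              sum(x$modules == "grey"), length(x$modules)))
  invisible(x)
}
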