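#' Remove unexpressed and blacklisted probes
#'
#' Drops probes that are not expressed on any array (all `expressed_flags`
#' FALSE across samples) and probes on an explicit blacklist (e.g., poorly
#' mapping probe sequences).  Retained values are never altered.
#'
#' @param raw An [expression_matrix()].
#' @param expressed_flags Logical probe-by-sample matrix conforming to
#'   `raw`, or `NULL` to derive flags as `values > floor`.
#' @param blacklist Character vector of probe IDs to remove.
#' @param floor Intensity floor used when `expressed_flags` is `NULL`.
#' @return A list with `matrix` (filtered [expression_matrix()]) and
#'   `report` (a `qc_report`: probe counts in/removed/out).
#' @export
filter_probes <- function(raw, expressed_flags = NULL, blacklist = character(0),
                          floor = 0) {
  stopifnot(inherits(raw, "expression_matrix"))
  if (is.null(expressed_flags)) {
    expressed_flags <- !is.na(raw$values) & raw$values > floor
  }
  if (!is.logical(expressed_flags) ||
      !identical(dim(expressed_flags), dim(raw$values)))
    stopf("expressed_flags must be a logical matrix with the shape of the data \
(%d x %d)", nrow(raw$values), ncol(raw$values))
  expressed_any <- rowSums(expressed_flags, na.rm = TRUE) > 0
  in_blacklist <- raw$probe_ids %in% blacklist
  keep <- expressed_any & !in_blacklist
  n_unexpr <- sum(!expressed_any)
  n_black <- sum(in_blacklist & expressed_any)  # count blacklist removals once
  if (!any(keep)) stopf("no probes survive filtering")
  out <- expression_matrix(raw$values[keep, , drop = FALSE],
                           raw$probe_ids[keep], raw$sample_ids, raw$scale_tag)
  report <- structure(list(
    n_probes_in = length(raw$probe_ids),
    n_probes_removed_unexpressed = n_unexpr,
    n_probes_removed_blacklist = n_black,
    n_probes_out = sum(keep),
    outlier_samples = character(0),
    sample_summary = data.frame(
      sample_id = raw$sample_ids,
      n_expressed = colSums(expressed_flags, na.rm = TRUE))),
    class = "qc_report")
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> probes in: %d; removed unexpressed: %d; removed blacklisted: %d; out: %d\n",
              x$n_probes_in, x$n_probes_removed_unexpressed,
              x$n_probes_removed_blacklist, x$n_probes_out))
  if (length(x$outlier_samples))
    cat("outlier samples:", paste(x$outlier_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the cross-column mean of
#' sorted values, with ranks preserved within columns and ties resolved by
#' averaging tied ranks (via [limma::normalizeQuantiles()]).  The operation
#' is idempotent.
#'
#' @param matrix An [expression_matrix()] without missing values.
#' @return An [expression_matrix()] on the same scale tag (or
#'   `normalized_log2` when the input was `log2`).
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (anyNA(matrix$values))
    stopf("missing values present; run filter_probes()/imputation before \
quantile normalization")
  norm <- limma::normalizeQuantiles(matrix$values, ties = TRUE)
  tag <- if (matrix$scale_tag == "log2") "normalized_log2" else matrix$scale_tag
  expression_matrix(norm, matrix$probe_ids, matrix$sample_ids, tag)
}

#' Log2 transform
#'
#' Elementwise log2 of a raw-intensity matrix.  Refuses matrices already on a
#' log2 scale (by `scale_tag`) and non-positive values.
#'
#' @param matrix An [expression_matrix()] with `scale_tag = "raw"`.
#' @return An [expression_matrix()] with `scale_tag = "log2"`.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale_tag != "raw")
    stopf("log2_transform expects raw-scale data; got scale_tag = \"%s\"",
          matrix$scale_tag)
  bad <- which(matrix$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-positive values cannot be log2 transformed (e.g., probe %s)",
          paste(unique(matrix$probe_ids[bad[, 1L]])[seq_len(min(5L, nrow(bad)))],
                collapse = ", "))
  expression_matrix(log2(matrix$values), matrix$probe_ids, matrix$sample_ids,
                    "log2")
}

#' Detect sample outliers by principal components
#'
#' Flags samples whose score on either of the first two principal components
#' lies more than `z_cutoff` standard deviations from the mean, and returns
#' an average-linkage sample dendrogram on 1 - Pearson correlation distance
#' for visual inspection.
#'
#' @param matrix An [expression_matrix()] with at least 3 samples.
#' @param z_cutoff Robustly liberal default of 4 SD.
#' @return A list with `outliers` (character vector of sample IDs), `scores`
#'   (samples x 2 PC z-score matrix) and `dendrogram` (an `hclust`).
#' @export
detect_outlier_samples <- function(matrix, z_cutoff = 4) {
  stopifnot(inherits(matrix, "expression_matrix"))
  x <- matrix$values
  if (ncol(x) < 3L) stopf("need >= 3 samples for outlier detection")
  if (all(apply(x, 1L, stats::sd) == 0)) stopf("constant matrix: no variation to analyze")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = 2L)
  z <- scale(pc$x[, 1:2, drop = FALSE])
  z[!is.finite(z)] <- 0  # degenerate PC (zero variance) cannot flag anyone
  out <- matrix$sample_ids[apply(abs(z) > z_cutoff, 1L, any)]
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "average")
  hc$labels <- matrix$sample_ids
  list(outliers = out, scores = z, dendrogram = hc)
}

#' Full expression preprocessing chain
#'
#' Convenience wrapper running the QC chain on raw intensities: probe
#' filtering, quantile normalization, log2 transform, and outlier flagging;
#' mirrors a standard array QC workflow (unexpressed-probe removal, quantile
#' normalization, log2 transformation, PCA/dendrogram inspection).
#'
#' @param raw An [expression_matrix()] on the raw intensity scale.
#' @param blacklist Probe IDs to remove regardless of expression.
#' @param floor Expression floor defining "expressed" for synthetic data.
#' @param z_cutoff Passed to [detect_outlier_samples()].
#' @return A list with `matrix` (normalized log2 [expression_matrix()]) and
#'   `report` (a `qc_report` including outlier samples).
#' @export
preprocess_expression <- function(raw, blacklist = character(0), floor = 0,
                                  z_cutoff = 4) {
  filtered <- filter_probes(raw, expressed_flags = NULL, blacklist = blacklist,
                            floor = floor)
  normalized <- quantile_normalize(log2_transform(filtered$matrix))
  outl <- detect_outlier_samples(normalized, z_cutoff = z_cutoff)
  filtered$report$outlier_samples <- outl$outliers
  list(matrix = normalized, report = filtered$report)
}
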