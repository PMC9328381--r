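#' Expression matrix container
#'
#' A probe-by-sample matrix of expression intensities together with its
#' measurement scale.  Rows are probes, columns are samples; both identifier
#' sets must be unique.  The `scale_tag` records where the matrix sits in the
#' preprocessing chain: `"raw"` (intensity scale, missing values permitted),
#' `"log2"` (log2-transformed) or `"normalized_log2"` (quantile-normalized and
#' log2-transformed; no missing values permitted).
#'
#' @param values Numeric matrix of expression values (probes x samples).
#' @param probe_ids Character vector of unique probe identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @param scale_tag One of `"raw"`, `"log2"`, `"normalized_log2"`.
#'
#' @return An object of class `expression_matrix` with fields `values`,
#'   `probe_ids`, `sample_ids`, `scale_tag`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale_tag = c("raw", "log2", "normalized_log2")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("expression values must be numeric")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids))
    stopf("row count (%d) != number of probe_ids (%d)", nrow(values), length(probe_ids))
  if (ncol(values) != length(sample_ids))
    stopf("column count (%d) != number of sample_ids (%d)", ncol(values), length(sample_ids))
  if (anyDuplicated(probe_ids))
    stopf("duplicate probe_ids: %s",
          paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample_ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (scale_tag != "raw" && anyNA(values))
    stopf("missing values are only permitted on the raw scale (scale_tag = \"raw\")")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 sample_ids = sample_ids, scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The file must be tab-separated with a header row of sample identifiers,
#' a first header cell `probe_id`, and one row per probe.  Values use `.` as
#' the decimal separator; missing values are encoded `NA` and are only
#' accepted for `scale_tag = "raw"`.
#'
#' @param path Path to a TSV file.
#' @param scale_tag Declared scale of the stored values (see
#'   [expression_matrix()]).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale_tag = "raw") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stopf("expression TSV needs a probe_id column plus >= 1 sample")
  probe_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(col %in% c("NA", "")))
    if (length(bad))
      stopf("non-numeric value '%s' at probe row %d, sample column '%s' in %s",
            col[bad[1L]], bad[1L], sample_ids[j], path)
    vals[, j] <- num
  }
  expression_matrix(vals, probe_ids, sample_ids, scale_tag)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the doubles exactly.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  chr <- formatC(x$values, digits = 17, format = "g")
  chr[is.na(x$values)] <- "NA"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("probe_id", x$sample_ids), collapse = "\t"), con)
  body <- apply(chr, 1L, paste, collapse = "\t")
  writeLines(paste(x$probe_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Paired probe-by-patient matrix of longitudinal expression changes
#'
#' Holds per-gene differences of log2 expression between the week-4 and
#' pretreatment samples of the same patient (equivalently, the log2 of the
#' intensity ratio).  Columns are restricted to patients with both timepoints.
#'
#' @param values Numeric matrix (probes x patients) of log2 differences.
#' @param probe_ids Unique probe identifiers.
#' @param patient_ids Unique patient identifiers.
#' @return An object of class `delta_matrix`.
#' @export
delta_matrix <- function(values, probe_ids = rownames(values),
                         patient_ids = colnames(values)) {
  values <- as.matrix(values)
  probe_ids <- as.character(probe_ids)
  patient_ids <- as.character(patient_ids)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(patient_ids))
    stopf("delta_matrix dimensions do not match identifier lengths")
  if (anyDuplicated(probe_ids) || anyDuplicated(patient_ids))
    stopf("delta_matrix identifiers must be unique")
  if (anyNA(values)) stopf("delta_matrix must not contain missing values")
  dimnames(values) <- list(probe_ids, patient_ids)
  structure(list(values = values, probe_ids = probe_ids, patient_ids = patient_ids),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("<delta_matrix> %d probes x %d patients (week4 - pretreatment, log2)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
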