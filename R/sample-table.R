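SAMPLE_TABLE_COLUMNS <- c("sample_id", "patient_id", "timepoint", "response",
                          "sex", "age_at_onset", "haq", "smoking",
                          "acpa_positive", "swollen28", "tender28", "crp",
                          "vas_global")

TIMEPOINT_LEVELS <- c("pretreatment", "week4")
RESPONSE_LEVELS <- c("good", "nonresponder")
SEX_LEVELS <- c("male", "female")
SMOKING_LEVELS <- c("never", "past", "current")

#' Per-sample clinical metadata table
#'
#' Validates a data frame of sample-level metadata for a paired two-timepoint
#' design: each patient contributes at most one `pretreatment` and one `week4`
#' sample, carries a single EULAR response label (`good` or `nonresponder`,
#' constant across the patient's samples), and baseline clinical covariates
#' (sex, age at disease onset, HAQ score, smoking habits, ACPA positivity,
#' 28-joint swollen/tender counts, CRP in mg/liter, 100-mm VAS global
#' assessment).
#'
#' @param df A data frame with columns `sample_id`, `patient_id`, `timepoint`,
#'   `response`, `sex`, `age_at_onset`, `haq`, `smoking`, `acpa_positive`,
#'   `swollen28`, `tender28`, `crp`, `vas_global`.
#' @return The validated data frame with class `sample_table` prepended.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SAMPLE_TABLE_COLUMNS, colnames(df))
  if (length(missing_cols))
    stopf("sample table is missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id values in sample table")

  check_vocab <- function(col, levels) {
    bad <- setdiff(unique(as.character(df[[col]])), levels)
    if (length(bad))
      stopf("unknown %s value(s): %s (allowed: %s)", col,
            paste(bad, collapse = ", "), paste(levels, collapse = "/"))
  }
  check_vocab("timepoint", TIMEPOINT_LEVELS)
  check_vocab("response", RESPONSE_LEVELS)
  check_vocab("sex", SEX_LEVELS)
  check_vocab("smoking", SMOKING_LEVELS)
  if (!is.logical(df$acpa_positive)) {
    v <- as.character(df$acpa_positive)
    if (!all(v %in% c("TRUE", "FALSE")))
      stopf("acpa_positive must be logical (TRUE/FALSE)")
    df$acpa_positive <- as.logical(v)
  }

  check_range <- function(col, lower, upper, integer = FALSE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stopf("missing or non-numeric values in %s", col)
    if (any(v < lower | v > upper))
      stopf("%s out of range [%s, %s]", col, lower, upper)
    if (integer && any(v != round(v))) stopf("%s must be integer-valued", col)
    df[[col]] <<- v
  }
  check_range("swollen28", 0, 28, integer = TRUE)
  check_range("tender28", 0, 28, integer = TRUE)
  check_range("vas_global", 0, 100)
  check_range("crp", 0, Inf)
  check_range("age_at_onset", 0, Inf)
  check_range("haq", 0, Inf)

  # paired design: at most one sample per patient x timepoint
  key <- paste(df$patient_id, df$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$patient_id[duplicated(key)][1L]
    stopf("patient '%s' has more than one sample at the same timepoint", dup)
  }
  n_resp <- tapply(as.character(df$response), df$patient_id,
                   function(r) length(unique(r)))
  if (any(n_resp > 1L))
    stopf("patient(s) with inconsistent response labels: %s",
          paste(names(n_resp)[n_resp > 1L], collapse = ", "))

  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample metadata table from TSV
#'
#' @param path Path to a tab-separated file whose columns follow the
#'   [sample_table()] schema.
#' @return A validated [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  sample_table(df)
}

#' Write a sample metadata table to TSV
#'
#' @param x A [sample_table()] (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair pretreatment and week-4 samples by patient
#'
#' Builds the paired index used for delta-expression features: for every
#' patient with a sample at both timepoints, the pretreatment and week-4
#' sample (and their column positions in the two matrices).  Patients with an
#' incomplete pair are dropped with a warning.  Patients are ordered
#' lexicographically so downstream fold assignment and outputs are
#' deterministic.
#'
#' @param expr_pre,expr_wk4 [expression_matrix()] objects holding the
#'   pretreatment and week-4 samples.  Their probe sets must be identical as
#'   sets (row order may differ).
#' @param samples A [sample_table()] covering every column of both matrices.
#' @return A data frame with columns `patient_id`, `pre_sample`, `wk4_sample`,
#'   `pre_col`, `wk4_col`, one row per fully paired patient.
#' @export
align_paired_design <- function(expr_pre, expr_wk4, samples) {
  stopifnot(inherits(expr_pre, "expression_matrix"),
            inherits(expr_wk4, "expression_matrix"))
  if (!setequal(expr_pre$probe_ids, expr_wk4$probe_ids))
    stopf("probe sets of the two expression matrices differ")
  all_cols <- c(expr_pre$sample_ids, expr_wk4$sample_ids)
  unknown <- setdiff(all_cols, samples$sample_id)
  if (length(unknown))
    stopf("sample column(s) absent from sample table: %s",
          paste(unknown, collapse = ", "))

  meta <- samples[match(all_cols, samples$sample_id), ]
  pre_meta <- meta[meta$timepoint == "pretreatment" &
                     meta$sample_id %in% expr_pre$sample_ids, ]
  wk4_meta <- meta[meta$timepoint == "week4" &
                     meta$sample_id %in% expr_wk4$sample_ids, ]
  patients <- sort(intersect(pre_meta$patient_id, wk4_meta$patient_id))
  incomplete <- sort(setdiff(union(pre_meta$patient_id, wk4_meta$patient_id),
                             patients))
  if (length(incomplete))
    warnf("dropping %d patient(s) without both timepoints: %s",
          length(incomplete), paste(incomplete, collapse = ", "))
  if (!length(patients)) stopf("no patient has both timepoints")

  pre_sample <- pre_meta$sample_id[match(patients, pre_meta$patient_id)]
  wk4_sample <- wk4_meta$sample_id[match(patients, wk4_meta$patient_id)]
  data.frame(patient_id = patients,
             pre_sample = pre_sample,
             wk4_sample = wk4_sample,
             pre_col = match(pre_sample, expr_pre$sample_ids),
             wk4_col = match(wk4_sample, expr_wk4$sample_ids),
             stringsAsFactors = FALSE)
}
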