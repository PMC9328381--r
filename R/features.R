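#' Feature matrix container
#'
#' A feature-by-patient matrix with a contrast tag recording which of the
#' model inputs it represents: pretreatment expression (`expr_pre`), week-4
#' expression (`expr_wk4`), the week-4 minus pretreatment log2 difference
#' (`expr_ratio` — identical to the log2 of the intensity ratio), or clinical
#' covariates at baseline / 3 months.
#'
#' @param values Numeric matrix (features x patients), no missing values.
#' @param feature_ids,patient_ids Unique identifiers.
#' @param contrast_tag One of `expr_pre`, `expr_wk4`, `expr_ratio`,
#'   `clinical_baseline`, `clinical_3mo`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_ids = rownames(values),
                           patient_ids = colnames(values),
                           contrast_tag = c("expr_pre", "expr_wk4", "expr_ratio",
                                            "clinical_baseline", "clinical_3mo")) {
  contrast_tag <- match.arg(contrast_tag)
  values <- as.matrix(values)
  feature_ids <- as.character(feature_ids)
  patient_ids <- as.character(patient_ids)
  if (anyNA(values)) stopf("feature matrix must not contain missing values")
  if (anyDuplicated(feature_ids)) stopf("feature_ids must be unique")
  if (nrow(values) != length(feature_ids) || ncol(values) != length(patient_ids))
    stopf("feature matrix dimensions do not match identifier lengths")
  dimnames(values) <- list(feature_ids, patient_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 patient_ids = patient_ids, contrast_tag = contrast_tag),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d patients [%s]\n",
              nrow(x$values), ncol(x$values), x$contrast_tag))
  invisible(x)
}

#' Week-4 minus pretreatment log2 expression differences
#'
#' For each paired patient, subtracts the pretreatment from the week-4 log2
#' expression profile.  On the log2 scale this difference equals the log2 of
#' the intensity ratio, hence "ratio" features.  Rows of the week-4 matrix
#' are realigned to the pretreatment probe order before subtraction, so the
#' operation is invariant to input row permutation.
#'
#' @param pre,wk4 [expression_matrix()] objects on a log2 scale with equal
#'   probe sets.
#' @param pairing Output of [align_paired_design()].
#' @return A [delta_matrix()] (probes x paired patients).
#' @export
delta_expression <- function(pre, wk4, pairing) {
  stopifnot(inherits(pre, "expression_matrix"),
            inherits(wk4, "expression_matrix"))
  if (!setequal(pre$probe_ids, wk4$probe_ids))
    stopf("probe sets differ between timepoints")
  need <- c("patient_id", "pre_col", "wk4_col")
  if (!all(need %in% colnames(pairing))) stopf("invalid pairing index")
  if (any(is.na(pairing$pre_col)) || any(is.na(pairing$wk4_col)))
    stopf("pairing references samples absent from the matrices")
  row_map <- match(pre$probe_ids, wk4$probe_ids)
  vals <- wk4$values[row_map, pairing$wk4_col, drop = FALSE] -
    pre$values[, pairing$pre_col, drop = FALSE]
  delta_matrix(vals, pre$probe_ids, pairing$patient_id)
}

#' Convert a delta matrix to ratio features
#'
#' @param delta A [delta_matrix()].
#' @return A [feature_matrix()] tagged `expr_ratio`.
#' @export
as_feature_matrix <- function(delta) {
  stopifnot(inherits(delta, "delta_matrix"))
  feature_matrix(delta$values, delta$probe_ids, delta$patient_ids, "expr_ratio")
}

#' Expression features at a single timepoint
#'
#' Extracts one column per paired patient from a timepoint's expression
#' matrix, producing the pretreatment or week-4 feature set.
#'
#' @param expr An [expression_matrix()].
#' @param pairing Output of [align_paired_design()].
#' @param timepoint `"pretreatment"` or `"week4"`.
#' @return A [feature_matrix()] tagged `expr_pre` or `expr_wk4`.
#' @export
timepoint_features <- function(expr, pairing, timepoint = c("pretreatment", "week4")) {
  timepoint <- match.arg(timepoint)
  col <- if (timepoint == "pretreatment") pairing$pre_col else pairing$wk4_col
  tag <- if (timepoint == "pretreatment") "expr_pre" else "expr_wk4"
  feature_matrix(expr$values[, col, drop = FALSE], expr$probe_ids,
                 pairing$patient_id, tag)
}

CLINICAL_FEATURES <- c("sex_female", "age_at_onset", "haq", "smoking_past",
                       "smoking_current", "acpa_positive", "swollen28",
                       "tender28", "crp", "vas_global")

#' Encode clinical covariates as model features
#'
#' Builds the 10-feature clinical design from the 9 source covariates: sex
#' and ACPA positivity as 0/1 indicators, smoking as two indicators (past,
#' current; never = reference), and age at onset, HAQ, swollen/tender joint
#' counts, CRP and VAS passed through numerically.  For the 3-month feature
#' set, pass `timepoint_tag = "clinical_3mo"` and a table carrying
#' `swollen28_3mo`, `tender28_3mo`, `crp_3mo`, `vas_global_3mo`, `haq_3mo`
#' (e.g., the `clinical` element of [simulate_cohort()]); time-invariant
#' covariates (sex, age at onset, smoking, ACPA) are reused.
#'
#' @param samples A [sample_table()] or per-patient clinical data frame.
#' @param timepoint_tag `"clinical_baseline"` or `"clinical_3mo"`.
#' @return A [feature_matrix()] (10 features x patients, lexicographic
#'   patient order).
#' @export
encode_clinical <- function(samples, timepoint_tag = c("clinical_baseline",
                                                       "clinical_3mo")) {
  timepoint_tag <- match.arg(timepoint_tag)
  df <- as.data.frame(samples)
  df <- df[!duplicated(df$patient_id), , drop = FALSE]
  df <- df[order(df$patient_id), , drop = FALSE]

  numeric_src <- c(age_at_onset = "age_at_onset", haq = "haq",
                   swollen28 = "swollen28", tender28 = "tender28",
                   crp = "crp", vas_global = "vas_global")
  if (timepoint_tag == "clinical_3mo") {
    m3 <- c(haq = "haq_3mo", swollen28 = "swollen28_3mo",
            tender28 = "tender28_3mo", crp = "crp_3mo",
            vas_global = "vas_global_3mo")
    missing3 <- setdiff(unname(m3), colnames(df))
    if (length(missing3))
      stopf("3-month covariate column(s) missing: %s",
            paste(missing3, collapse = ", "))
    numeric_src[names(m3)] <- m3
  }
  need <- c("patient_id", "sex", "smoking", "acpa_positive", unname(numeric_src))
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stopf("missing covariate column(s): %s", paste(missing_cols, collapse = ", "))
  for (cc in unname(numeric_src)) {
    if (anyNA(df[[cc]]))
      stopf("missing %s for patient(s): %s", cc,
            paste(df$patient_id[is.na(df[[cc]])], collapse = ", "))
  }

  vals <- rbind(
    sex_female = as.numeric(df$sex == "female"),
    age_at_onset = as.numeric(df[[numeric_src["age_at_onset"]]]),
    haq = as.numeric(df[[numeric_src["haq"]]]),
    smoking_past = as.numeric(df$smoking == "past"),
    smoking_current = as.numeric(df$smoking == "current"),
    acpa_positive = as.numeric(df$acpa_positive),
    swollen28 = as.numeric(df[[numeric_src["swollen28"]]]),
    tender28 = as.numeric(df[[numeric_src["tender28"]]]),
    crp = as.numeric(df[[numeric_src["crp"]]]),
    vas_global = as.numeric(df[[numeric_src["vas_global"]]]))
  feature_matrix(vals[CLINICAL_FEATURES, , drop = FALSE], CLINICAL_FEATURES,
                 df$patient_id, timepoint_tag)
}

#' Fit a leakage-safe standardizer on training patients
#'
#' Estimates per-feature means and SDs on the training subset only.
#' Zero-variance (constant) features are dropped with a warning, so the
#' standardized design is full rank in the degenerate direction.
#'
#' @param features A [feature_matrix()].
#' @param training_patients Character vector of patient IDs (non-empty subset
#'   of the matrix's patients).
#' @return An object of class `standardizer` with fields `feature_ids`,
#'   `mean`, `sd`, `dropped`.
#' @export
fit_standardizer <- function(features, training_patients) {
  stopifnot(inherits(features, "feature_matrix"))
  training_patients <- as.character(training_patients)
  if (!length(training_patients)) stopf("training set is empty")
  missing_pat <- setdiff(training_patients, features$patient_ids)
  if (length(missing_pat))
    stopf("training patient(s) absent from features: %s",
          paste(missing_pat, collapse = ", "))
  x <- features$values[, training_patients, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  dropped <- features$feature_ids[sdv == 0 | !is.finite(sdv)]
  if (length(dropped))
    warnf("dropping %d zero-variance feature(s): %s", length(dropped),
          paste(utils::head(dropped, 5L), collapse = ", "))
  keep <- setdiff(features$feature_ids, dropped)
  if (!length(keep)) stopf("no features left after dropping zero-variance features")
  structure(list(feature_ids = keep, mean = mu[keep], sd = sdv[keep],
                 dropped = dropped),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Centers and scales every patient's features with the training-set
#' parameters stored in `params` — never with statistics of the data being
#' transformed.
#'
#' @param params A `standardizer` from [fit_standardizer()].
#' @param features A [feature_matrix()] containing at least the standardizer's
#'   features.
#' @return A [feature_matrix()] restricted to the standardizer's features.
#' @export
apply_standardizer <- function(params, features) {
  stopifnot(inherits(params, "standardizer"), inherits(features, "feature_matrix"))
  missing_feat <- setdiff(params$feature_ids, features$feature_ids)
  if (length(missing_feat))
    stopf("features absent from matrix: %s", paste(missing_feat, collapse = ", "))
  x <- features$values[params$feature_ids, , drop = FALSE]
  x <- (x - params$mean) / params$sd
  feature_matrix(x, params$feature_ids, features$patient_ids,
                 features$contrast_tag)
}
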