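#' Disease Activity Score in 28 joints using CRP (DAS28-CRP)
#'
#' Computes the standard DAS28-CRP composite:
#' \deqn{0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.36\ln(CRP+1) + 0.014\,VAS + 0.96}
#' where TJC28/SJC28 are 28-joint tender and swollen counts, CRP is in
#' mg/liter and VAS is the patient global assessment on a 100-mm visual
#' analog scale.  With all components at zero the score is 0.96, the formula's
#' floor.
#'
#' @param tender28,swollen28 Joint counts in \[0, 28\].
#' @param crp C-reactive protein, mg/liter (non-negative).
#' @param vas_global Patient global assessment, mm in \[0, 100\].
#' @return Numeric DAS28-CRP score(s); vectorized over the inputs.
#' @export
compute_das28_crp <- function(tender28, swollen28, crp, vas_global) {
  if (any(crp < 0)) stopf("CRP must be non-negative (mg/liter)")
  if (any(tender28 < 0 | tender28 > 28) || any(swollen28 < 0 | swollen28 > 28))
    stopf("joint counts must lie in [0, 28]")
  if (any(vas_global < 0 | vas_global > 100))
    stopf("vas_global must lie in [0, 100] mm")
  0.56 * sqrt(tender28) + 0.28 * sqrt(swollen28) +
    0.36 * log(crp + 1) + 0.014 * vas_global + 0.96
}

#' EULAR response category from a DAS28 trajectory
#'
#' Applies the standard EULAR response grid to the baseline and month-6
#' DAS28 scores.  With `improvement = baseline - month6`:
#' `good` requires `improvement > 1.2` and `month6 <= 3.2`;
#' `none` holds when `improvement <= 0.6`, or `improvement <= 1.2` with
#' `month6 > 5.1`; everything else is `moderate`.  The classic 3.2/5.1
#' absolute thresholds are used (no CRP-specific recalibration).
#'
#' @param das28_baseline,das28_month6 DAS28 scores at baseline and 6 months.
#' @return Character vector in `{"good", "moderate", "none"}`.
#' @export
eular_category <- function(das28_baseline, das28_month6) {
  if (any(!is.finite(das28_baseline)) || any(!is.finite(das28_month6)))
    stopf("DAS28 scores must be finite")
  imp <- das28_baseline - das28_month6
  out <- rep("moderate", length(imp))
  out[imp > 1.2 & das28_month6 <= 3.2] <- "good"
  out[imp <= 0.6 | (imp <= 1.2 & das28_month6 > 5.1)] <- "none"
  out
}
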