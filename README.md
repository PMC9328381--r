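# mtxresponse

Early transcriptomic classification of methotrexate (MTX) nonresponse in
rheumatoid arthritis from paired whole-blood expression profiles.

About a third of RA patients started on low-dose MTX gain no benefit, but
efficacy is conventionally judged only after 6 months.  `mtxresponse`
implements an analysis pipeline for a paired two-timepoint design —
expression measured pretreatment and 4 weeks after MTX initiation, response
labeled at 6 months by EULAR criteria (good responder vs nonresponder) —
asking whether the early *change* in expression classifies eventual
nonresponse.

The package provides three analysis legs plus a synthetic cohort generator
that emulates the study design, so everything is testable without access to
patient data:

- **Delta-expression classifiers.** Per-gene features
  `delta[g, p] = log2 expr(week 4) - log2 expr(pretreatment)` (the log2 of
  the intensity ratio), classified under 10-fold-outer / 5-fold-inner nested
  cross-validation with per-fold standardization. Three model families: L2
  (ridge) logistic regression, random forest, and pathway-aggregated L2.
  Performance is reported as mean ± SEM of balanced accuracy and ROC AUC
  across outer folds; feature importance as mean ± SD of coefficients.
- **Weighted coexpression networks**, built from scratch: Pearson
  correlation, unsigned soft-thresholded adjacency `|cor|^beta` (beta chosen
  by the scale-free topology criterion), topological overlap

  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,

  average-linkage clustering of `1 - TOM` with an adaptive (dynamic) tree
  cut, consensus-versus-group module comparison by hypergeometric overlap,
  per-gene connectivity `k_i = sum_j a_ij`, and top-20% hub genes per
  module.  Modules detected in nonresponders but unassigned (grey) in the
  consensus network are reported as nonresponder-specific.
- **Hypergeometric over-representation** of module/hub gene lists against
  GMT gene sets, with BH adjustment and a file-based prior-coexpression
  evidence check.
- **Synthetic cohorts** (`simulate_cohort()`): planted latent-factor
  coexpression modules (optionally restricted to nonresponders), a planted
  standardized week-4 expression shift in nonresponders, and clinical
  covariates matching the published cohort table, with EULAR labels computed
  from simulated DAS28-CRP trajectories
  (`0.56*sqrt(TJC) + 0.28*sqrt(SJC) + 0.36*ln(CRP+1) + 0.014*VAS + 0.96`).

See the methods vignette (`vignettes/mtxresponse-methods.Rmd`) for the model
assumptions, parameter defaults and design decisions.

## Worked example

```r
library(mtxresponse)

cohort  <- simulate_cohort(simulation_config(n_genes = 2000, seed = 1))
pairing <- align_paired_design(cohort$expr_pre, cohort$expr_wk4, cohort$samples)
ratio   <- as_feature_matrix(delta_expression(cohort$expr_pre, cohort$expr_wk4, pairing))
labels  <- setNames(as.character(cohort$clinical$response), cohort$clinical$patient_id)

cv <- nested_cv(ratio, labels[ratio$patient_ids], model_spec("l2_logistic"), seed = 1)
cv
#> <cv_result> l2_logistic, 10-fold outer / 5-fold inner nested CV
#>   balanced accuracy: 0.920 +/- 0.026 (mean +/- SEM)
#>   ROC AUC:           0.984 +/- 0.013 (mean +/- SEM)
```

The simulated cohort plants 50 signal genes with a standardized delta
effect of 1.0 between response groups, so the ratio classifier should — and
does — separate the groups far above chance; with `signal_effect = 0` the
same pipeline is calibrated to AUC ≈ 0.5.  Coefficients are summarized
across folds (mean ± SD), with the largest magnitudes corresponding to
planted signal genes:

```r
head(cv$coefficient_summary, 3)
#>      feature       mean         sd n_folds
#> 1365  g01365 0.10063574 0.04254770      10
#> 1908  g01908 0.09337210 0.03551910      10
#> 1818  g01818 0.08825366 0.03665458      10
```

Group-restricted coexpression: build per-group and consensus networks on
the pretreatment samples, then ask which nonresponder modules are grey
(unassigned) in consensus.  The two planted nonresponder-only modules (80
and 60 genes) are recovered with grey fraction 1:

```r
is_nr <- cohort$samples$response[match(cohort$expr_pre$sample_ids,
                                       cohort$samples$sample_id)] == "nonresponder"
net <- consensus_modules(list(good = cohort$expr_pre$values[, !is_nr],
                              nonresponder = cohort$expr_pre$values[, is_nr]),
                         beta = 6)
detect_group_specific_modules(net$per_group$nonresponder$assignment,
                              net$consensus$assignment)
#>   module size n_grey_in_consensus grey_fraction p_grey_overlap
#> 3     M3   83                  83             1   1.196427e-05
#> 4     M4   61                  61             1   2.537847e-04
```

`run_pipeline(pipeline_config(...))` chains all stages (simulate →
preprocess → features → classify → network → enrich) and writes TSV
artifacts plus a manifest with seeds, parameters and MD5 checksums;
reruns with the same configuration reproduce the checksums exactly.

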