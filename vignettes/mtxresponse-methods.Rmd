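---
title: "Methods: delta-expression classification and coexpression network analysis of methotrexate nonresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-expression classification and coexpression network analysis of methotrexate nonresponse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxresponse)
```

## The problem

Roughly a third of rheumatoid arthritis (RA) patients started on low-dose
methotrexate (MTX) do not benefit, yet the decision to escalate therapy is
conventionally deferred until 6 months.  An early molecular readout of
likely nonresponse would let those patients be fast-tracked to alternative
therapy.  `mtxresponse` implements an analysis pipeline for paired
whole-blood expression profiles taken before treatment and 4 weeks after
MTX initiation, with the 6-month EULAR response category (good responder vs
nonresponder) as the classification target.  The pipeline has three
scientific legs:

1. **Delta-expression classification.** For each gene, the difference of
   log2 expression between week 4 and pretreatment (equivalently the log2
   of the intensity ratio) is a per-patient feature.  Three model families
   — L2-regularized logistic regression, random forest, and a
   pathway-aggregated linear model — are compared under nested
   cross-validation.
2. **Weighted coexpression network analysis.** Modules of coexpressed
   genes are detected separately in nonresponders and in the consensus of
   both response groups; modules present in nonresponders but unassigned
   (grey) in consensus are candidates for group-restricted biology.
3. **Over-representation analysis.** Module hub genes are tested for
   enrichment against gene-ontology-style gene sets by the hypergeometric
   upper tail, with external coexpression evidence summarized per module.

Because no cohort expression data are publicly deposited for this design,
the package is exercised end-to-end on a synthetic cohort generator that
emulates the study's structure; every downstream claim the test suite makes
is therefore a *property* claim (oracle equivalence, planted-structure
recovery, null calibration), not a reproduction of cohort-specific numbers.

## The synthetic cohort generator

`simulate_cohort()` draws a paired two-timepoint cohort under a
latent-factor model.  Defaults are the study's design: 42 good responders,
43 nonresponders, two arrays per patient.

**Expression.** Each gene has a baseline log2 abundance drawn from
N(7.5, 1.2²) and i.i.d. Gaussian array noise with `noise_sd = 0.3` log2
units — a typical residual scale for quantile-normalized arrays.  A planted
module *m* with correlation target *r* has one latent factor per array;
member genes load on it with
`lambda = noise_sd * sqrt(r / (1 - r))`, which makes the expected
within-module Pearson correlation exactly *r*.  Modules declared
`nonresponder_only` have their factor active only in nonresponder arrays,
so they form a module in the nonresponder network and dissolve into noise
in good responders.

**Longitudinal signal.** `n_signal_genes` genes (drawn outside the planted
modules, so the two kinds of planted structure can be assessed
independently) receive a week-4 mean shift in nonresponders with
alternating sign across genes.  The shift is
`signal_effect * sqrt(2) * noise_sd`: since the week-4 minus pretreatment
difference carries noise from two arrays (SD `sqrt(2) * noise_sd`), this
makes `signal_effect` the *standardized* between-group effect on the delta
scale, which is the scale the classifier works on.

**Clinical covariates.** Per-group distributions follow the published
pretreatment cohort table: female proportion 0.76/0.77, age at onset
N(59, 15²)/N(55, 14²), HAQ and VAS as truncated normals with SDs converted
from IQRs (IQR/1.35), smoking as a categorical with the published
never/past/current counts, ACPA positivity 0.64/0.58, and joint counts
modeled as normals on the square-root scale (then squared, rounded and
clamped to 0–28), matching the right-skew of count data.

**CRP and DAS28 calibration.** The published CRP summary ("2.2 ± 1
mg/liter") is not usable as a raw mg/liter scale for an active-RA cohort,
so CRP is modeled log-normally with `sd(ln CRP) = 1`, and its *location* is
calibrated: `calibrate_crp_location()` solves, by deterministic quadrature
and root finding, for the ln-CRP mean that makes the expected DAS28-CRP
computed from the simulated components equal the published group means (4.8
good, 4.0 nonresponders).  This keeps the components internally consistent
with the DAS28-CRP formula

$$\mathrm{DAS28} = 0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.36\ln(CRP+1) + 0.014\,\mathrm{VAS} + 0.96$$

while reproducing the group-level disease activity exactly in expectation.
The calibrated CRP medians (about 15 mg/liter in good responders, 5 in
nonresponders) are clinically plausible for recent-onset RA.

**EULAR labels.** The response label is *computed*, not assigned: a month-6
DAS28 is simulated by drawing a treatment improvement from a group-specific
normal, and `eular_category()` applies the standard EULAR grid
(good: improvement > 1.2 and endpoint ≤ 3.2; none: improvement ≤ 0.6, or
≤ 1.2 with endpoint > 5.1; else moderate).  The classic 3.2/5.1 absolute
thresholds are used even though the score is DAS28-CRP, as no CRP-specific
grid is specified for this design.  Two modeling details matter:

* The improvement is drawn *conditionally on the baseline* (a truncated
  normal over the region that yields the intended category).  Naive
  rejection sampling of (baseline, improvement) pairs would select against
  high-baseline good responders and bias the retained baseline DAS28
  distribution away from its calibrated mean.
* Moderate responders are not emitted, mirroring a two-group study design;
  the improvement distributions (good: N(2.4, 0.8²) truncated to the good
  region; nonresponders: N(0.15, 0.55²) truncated at 0.6) are chosen so
  that truncation is mild.

Month-3 covariates, used by the `clinical_3mo` feature set, shrink each
baseline component toward remission in proportion to a partially realized
(≈70%) fraction of the patient's 6-month improvement, plus measurement
noise.

**What the generator does not emulate:** probe-level array artifacts
(bead-level noise, detection p-values), batch effects, heavy-tailed or
gene-specific noise variances, correlated module factors, and any
gene-identity biology (the interferon signature is representable only as
"a planted module").  Passing tests therefore demonstrate that the
*machinery* is correct and calibrated, not that real cohorts will yield
comparable effect sizes.

## Preprocessing

`preprocess_expression()` follows standard array QC: probes not expressed
on any array (operationalized for synthetic data as intensity above a
configurable floor, since no detection p-values exist) and blacklisted
probes are removed; values are log2-transformed and quantile normalized
(`limma::normalizeQuantiles`, tied ranks averaged, which makes the
operation idempotent including on ties); sample outliers are flagged when
either of the first two principal component scores exceeds `z_cutoff = 4`
SDs, with an average-linkage correlation dendrogram returned for
inspection.  The PCA rule replaces "visual inspection" with an automatic,
testable criterion; 4 SD is deliberately liberal so that homogeneous
cohorts are essentially never flagged.

## Classification

**Features.** Five contrasts are supported: pretreatment expression,
week-4 expression, the week-4 minus pretreatment log2 difference
(`expr_ratio`), and clinical covariates at baseline or month 3.  The nine
clinical covariates expand to ten features (sex and ACPA as 0/1, smoking
as past/current indicators against a never-smoker reference, six numeric
covariates passed through).

**Nested cross-validation.** `nested_cv()` uses 10 stratified outer folds;
within each outer training set, features are standardized with parameters
fit on that training set only (zero-variance features dropped), an inner
stratified 5-fold loop chooses hyperparameters by mean inner ROC AUC, the
model is refit on the full training set, and held-out patients are scored
once.  Standardization is refit inside every outer fold — the leakage-safe
reading of "standardization was applied to all input data" — and the test
suite asserts by checksum comparison that no training artifact changes
when held-out values are corrupted.  Per-outer-fold seeds are derived up
front so each fold is independently reproducible.

**Families and grids.** The L2 family uses `glmnet` (ridge, binomial) with
seven log-spaced penalties `10^{3, 2, …, -3}`; ties in inner AUC resolve
toward the stronger penalty.  The random forest family uses
`randomForest` with `{200, 500}` trees × `{unlimited, depth 8}` (as a
`maxnodes = 2^8` cap) and `sqrt(p)` features per split.  The
pathway-supported family averages standardized member-gene features per
pathway (`pathway_aggregate()`, size floor 3) and feeds the result to the
L2 grid; this mean-aggregation is an explicit, simple proxy for more
elaborate pathway-supported learners and is labeled as such.

**Reporting.** Balanced accuracy (mean of per-class recalls, at the 0.5
posterior threshold) and ROC AUC (Mann–Whitney form; ties credit 1/2;
constant scores return 0.5 with a warning) are summarized as mean ± SEM
over the 10 outer folds, with SEM = SD/√10.  Linear-family coefficients
are summarized feature-wise as mean ± SD across folds.
`nonresponder_detection_curve()` re-expresses the pooled held-out score
sweep as the fraction of true nonresponders detected versus the fraction
of good responders misclassified — the clinically relevant trade-off when
high nonresponder recall is preferred.  (The underlying figure axis this
mirrors is ambiguous about which class's error rate is plotted; the
responders-misclassified reading is adopted because it matches the
published summary of detecting about half of nonresponders at a ~20%
cost.)

## Coexpression networks

All network machinery is implemented in the package, since it is the
analytic core: Pearson correlation across samples; unsigned soft
thresholding `a_ij = |cor_ij|^beta` with zero diagonal; connectivity
`k_i = sum_j a_ij`; and unsigned topological overlap

$$TOM_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}},\qquad TOM_{ii}=1.$$

`soft_threshold()` implements the scale-free topology criterion: for each
candidate power (default grid 1–20) it bins the connectivity distribution
into 10 bins and regresses log10 p(k) on log10 mean(k); the smallest power
with R² ≥ 0.85 is chosen, with a flagged fall-back to the maximal-R² power
when the target is unreachable (e.g., structureless data).  For planted
fixture work a fixed `beta = 6` — the conventional unsigned default — is
used so the network stage is fully deterministic.

**Dynamic tree cut.** Modules come from average-linkage clustering of
`1 - TOM` followed by an adaptive branch decomposition
(`cluster_and_cut()`): walking down from the root, a branch becomes a
module when it (i) has ≥ `min_module_size` (default 30) genes, (ii)
completes below the 0.99 quantile of merge heights, and (iii) is separated
from the rest of the tree by a merge-height gap of at least `min_gap_frac`
(default 0.02) of the dendrogram height range; otherwise its children are
examined.  Leaves not captured by any qualifying branch are grey
(unassigned).  The gap criterion is what keeps unstructured data grey: in
noise dendrograms average linkage concentrates the late merges, so
size-30+ branches sit within ≲0.2% of the height range of their
attachment point, whereas planted modules at correlation 0.6 separate by
≳8% of the range; 0.02 sits an order of magnitude from both regimes.
Module labels are ordered by decreasing size; hub selection takes the top
20% (ceiling) of each module by whole-network connectivity, ties broken
lexicographically.

**Consensus and group-specific modules.** The default consensus
construction builds one TOM per response group, quantile-matches them with
a power transform so their 95th percentiles agree (a power transform
preserves [0,1] and monotonicity, unlike multiplicative scaling), and
takes the elementwise minimum; the reference quantile is the *smallest*
group quantile, so scaling only ever shrinks a structured TOM toward the
weakest group and can never inflate an unstructured group's background
into apparent consensus.  Pooling both groups' samples into a single
network is available as `approach = "pooled"`.  A nonresponder module is
called group-specific (`detect_group_specific_modules()`) when more than
half of its members are grey in consensus, reported with the grey fraction
and a hypergeometric enrichment of the module in the consensus grey set
rather than as a bare yes/no.

## Enrichment

`hypergeometric_enrichment()` computes upper-tail hypergeometric P values
(`P(X ≥ k)` via `stats::phyper`) for a query list against a gene-set
collection restricted to the analysis universe (all genes surviving
preprocessing, by default) and size-filtered to 10–2000 members.
Benjamini–Hochberg q-values are reported alongside raw P values.  Headline
P values of the motivating analysis (e.g., interferon-pathway
enrichments around 10^-25) depend on the cohort and annotation release and
are not reproduction targets.  External evidence lookup is file-based:
`prior_coexpression_fraction()` takes user-supplied unordered evidence
pairs and reports, per module, the fraction of hub genes with at least one
evidence partner inside the same hub set.

## Numerical and design choices

* Patient ordering is lexicographic everywhere, making fold assignment and
  outputs deterministic; all stochastic steps are seeded, and the pipeline
  derives per-stage seeds from one global seed.
* Quantile-normalization ties are averaged; TSV interchange uses 17
  significant digits so write/read round-trips are bit-exact.
* AUC tie handling follows the Mann–Whitney ½ convention; the degenerate
  all-constant-score case returns 0.5 with a warning rather than erroring,
  since it legitimately occurs for saturated folds.
* Adjacency diagonals are fixed at zero so connectivity is a sum over
  *other* genes; TOM then needs no explicit diagonal exclusion.
* Genes that become constant within a group after quantile normalization
  (possible for rank-stable genes in small cohorts) are excluded from the
  network stage with a warning, since their correlations are undefined.
* The test suite and the acceptance script run at reduced problem sizes
  chosen to preserve the structure under test: 2,000 genes × 60 samples
  for module recovery, 5,000 genes × 85 patients for the signal classifier
  condition, 800 genes × 85 patients × 20 cohorts for the null
  calibration, and 10,000 patients per group for clinical summary
  recovery.  These sizes are the package's own choices for exercising each
  property at full strength.

## Known limitations

* The cohort is synthetic; absolute performance numbers produced by the
  examples characterize the generator's conditions, not any real cohort.
* The pathway-supported family is a mean-aggregation proxy, not a
  reimplementation of any specific published pathway learner.
* The tree-cut variant is a dendrogram-based adaptive decomposition with
  its own separation parameter; it is contract-compatible with, but not
  identical to, other dynamic tree-cut implementations.
* Module eigengenes, eigengene–trait correlation, preservation statistics
  and GO-graph propagation are out of scope.
* One published figure's error-rate axis is ambiguous; the detection curve
  adopts the responders-misclassified reading (see above) and exposes the
  full threshold sweep so either convention can be recomputed.
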