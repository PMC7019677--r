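---
title: "Methods: evaluating down-regulated salivary mRNA markers for OSCC screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating down-regulated salivary mRNA markers for OSCC screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivadx)
```

## The problem

Oral squamous cell carcinoma (OSCC) is usually diagnosed late, and saliva is
an attractive screening medium because it bathes the lesion. A recurring
study design measures candidate mRNAs in whole saliva by qPCR in a small
case-control cohort, normalises each transcript to a housekeeping gene
(GAPDH), and asks two questions: which transcripts differ between groups,
and how well do they — singly or in combination — discriminate patients from
controls? `salivadx` implements that full analysis as a reusable, seeded
pipeline for panels of *down-regulated* markers: transcripts whose salivary
level falls in cancer.

The package ships calibrated to a six-marker panel (MAOB, NAB2, COL3A1,
NPIPB4, CYP27A1, SIAE) measured in 34 controls and 33 OSCC patients, the
group-level summary statistics of which are embedded as the default
synthetic-cohort configuration (`table2_defaults()`).

## Relative quantification (2^-ddCt)

qPCR reports a cycle threshold (Ct) per well; lower Ct means more template.
With triplicate wells the pipeline averages Ct arithmetically per
(sample, gene) (`average_ct()`), normalises to the same sample's reference
gene, dCt = Ct(gene) − Ct(GAPDH) (`delta_ct()`), subtracts a calibrator dCt
per gene, and reports relative expression 2^−ddCt (`rel_expression()`,
`quantify_table()`). Amplification efficiency is fixed at 2 (one doubling
per cycle); no efficiency correction is attempted, and raw fluorescence
processing is out of scope.

The calibrator — the point where relative expression equals 1 — is a policy
object. The default is the per-gene mean dCt of the control group, which
makes the control group the interpretive baseline; a named reference sample,
explicit per-gene values, or no calibration (2^−dCt) are also available.
Between-group *fold changes are calibrator-invariant* (the calibrator
cancels in the ratio), a property the test suite asserts, so this choice
affects only the reporting scale. Undetermined replicates are dropped from
the mean; a cell with no usable replicate stays missing and downstream
statistics use complete cases per gene; samples without the reference gene
cannot be normalised and are excluded with a logged reason.

## Group comparison and the "low level" call rule

For each gene the pipeline reports group means and sample SDs (n−1
denominator, the convention of R's `sd()`), the fold change
case-mean/control-mean, and a two-sided Wilcoxon rank-sum p-value
(`summarize_genes()`). The rank-sum test is used unconditionally — in this
design salivary expression is right-skewed and fails Shapiro-Wilk normality
(`normality_test()` is provided for that diagnostic) — with exact
enumeration when the pooled sample size is at most 12 and no ties are
present, and the tie- and continuity-corrected normal approximation
otherwise. No multiple-testing adjustment is applied by default, matching
the single-cohort, six-marker reporting convention; `p.adjust()` can be
applied downstream if wanted.

The diagnostic call rule marks a sample "low level" (suggestive of cancer)
for a gene when its expression is **strictly below** the control mean minus
one control SD (`call_low_high()`). Values exactly at the cut-off are
"high": the rule is stated as "below", and on continuous data boundary ties
have probability zero, so the strict reading is adopted. On Gaussian
control data this rule's specificity converges to Phi(1) ≈ 0.841 as the
control sample grows — a calibration property the acceptance suite verifies
by Monte Carlo at n = 100,000. Reported tables round to two decimals
(`format_gene_summary()`); computation is always at full precision. With
the packaged calibration this reproduces the published cut-offs (e.g. NAB2
2.11 − 0.42 = 1.69, SIAE 1.18 − 0.24 = 0.94); note that a few published
cells (the MAOB cut-off and fold change, the NPIPB4 cut-off, the CYP27A1
fold change) differ from full-precision arithmetic by one unit in the last
printed digit — presumably rounded from unrounded means — and the pipeline
deliberately reports the full-precision values.

Cohort-balance checks for 2×2 covariate tables use the uncorrected Pearson
chi-square (`contingency_test()`); Yates continuity correction is available
behind a flag but off by default, the uncorrected statistic being the one
that reproduces the published smoking (p ≈ 0.94) and alcohol (p ≈ 0.68)
comparisons.

## ROC analysis

`empirical_roc()` builds the empirical ROC curve with one point per
distinct score (ties grouped), thresholds at midpoints between consecutive
distinct scores with ±Inf sentinels, and endpoints (0,0) and (1,1). AUC is
the trapezoidal area, which equals the Mann-Whitney probability of correct
pair ordering with half credit for ties — the suite checks this identity
against an O(n²) pairwise-counting oracle and against pROC. Markers here
are *lower* in disease, so the default orientation (`direction = "low"`)
negates scores internally and reported AUCs are ≥ 0.5 for markers that
behave as expected; the orientation is recorded in every result.

Operating points use the Youden-optimal threshold (maximum
sensitivity + specificity − 1), with ties broken toward higher sensitivity
and then the lower threshold. The selection rule behind published
sensitivity/specificity pairs for this kind of table is rarely stated;
Youden is the field-standard choice and is documented as an assumption, so
published operating points are not treated as reproduction targets.

Confidence intervals are percentile bootstrap intervals with resampling
stratified by class (cases and controls resampled separately, so no
replicate loses a class), B = 2000 by default, seeded and reproducible.
The acceptance suite checks 92–98% empirical coverage of a true AUC of 0.8
at the study's group sizes (34/33) over 500 replicate datasets. DeLong-type
analytic intervals are deliberately not implemented; the bootstrap is the
package's single CI method.

## Greedy AUC-ordered panel combination

The combination algorithm builds multi-marker panels greedily:

1. compute each candidate's univariate empirical AUC;
2. order candidates from largest to smallest AUC (ties broken by larger
   standardised mean difference, then gene name, and logged);
3. fit a logistic regression of case status on the top two candidates and
   use its linear predictor as the combined risk score;
4. add the next-ranked candidate and refit; repeat until all candidates are
   included.

All intermediate panels are returned with in-sample AUCs
(`greedy_combine()`, `evaluate_panels()`). Each step *refits all
coefficients jointly*: "combine with the next biomarker" is read as
enlarging the logistic model, which is the standard forward-inclusion
reading; a "frozen" variant (previous risk score entered as a single
covariate beside the new marker) is available via `method = "frozen"` for
sensitivity analysis. The intercept is always included and there is no
regularisation by default (n = 67, at most 6 markers); a ridge penalty
(`ridge =`, via glmnet) exists for separation-prone synthetic data. Markers
enter on the relative-expression scale by default with a `log2_transform`
flag, since the scale entering the regression is a free choice in this
design. Complete or quasi-complete separation — common on well-separated
synthetic cohorts — is flagged with a warning; the final-iterate
coefficients still define a valid ranking, so the risk score's AUC remains
well-defined. Evaluation is in-sample (apparent AUC), matching how such
panels are first reported; no cross-validation is applied to the headline
numbers, and the optimism of apparent AUC at n = 67 is a known limitation.
Specific panels of interest (e.g. CYP27A1 + SIAE) can be fitted directly
with `fit_marker_sets()` rather than through the greedy path.

## Age-stratified re-analysis

Diagnostic accuracy in this design varies with age, so `run_pipeline()`
repeats the whole analysis within age strata (`stratified_analysis()`).
The default split is at 60 years — close to the cohort mean age and chosen
to balance stratum sizes — with "under 60" meaning age < 60 and the older
stratum taking age ≥ 60, so the strata partition the cohort exactly (a
tested invariant). Within each stratum the diagnostic cut-offs are
recomputed from that stratum's own controls — stratum cut-offs therefore
differ from the overall ones whenever expression drifts with age — and ROC
and panel building are rerun. A stratum that is empty or retains a single
class is skipped with a warning.

## The synthetic-cohort generator

No per-subject data are published for this design, so the generator
(`simulate_cohort()`) emulates the cohort from group-level statistics:

* **Expression**: per gene and group, log-normal draws whose two parameters
  are solved from the configured mean and SD (moment matching). The
  log-normal is a stand-in: relative expression is positive and
  right-skewed and the real data were non-normal, but the true per-subject
  distributions are unknown. A zero-truncated normal is available behind
  `distribution = "truncated-normal"` for sensitivity checks (its moments
  are approximate only when the mean is near zero).
* **Ages**: normal truncated to the observed range per group
  (control 53.2 ± 17.4 years on 25–83; case 61.2 ± 18.1 on 24–97) by
  inverse-CDF sampling.
* **Covariates**: independent Bernoulli draws at the cohort's rates for
  sex, smoking, alcohol and mild periodontitis, with no expression
  dependence by default (none was detected in the source design).
* **Age effect**: optional per-gene slope (expression units/year), applied
  as a mean-preserving shift around the group age mean; default 0 because
  the source design reports but does not model the age interaction. A
  strong negative slope can push draws non-positive; such values are
  floored at the smallest positive double with a warning, preserving the
  positivity invariant.
* **Seeding**: one master seed, with per-(gene, group) substreams derived
  deterministically from hashed keys, so adding a gene never perturbs
  existing genes' draws and identical configurations are bitwise
  reproducible.

`simulate_ct_plate()` inverts the quantification — Ct = reference Ct +
calibrator dCt − log2(expression) plus optional Gaussian replicate noise —
so the qPCR module can be round-trip tested: at zero replicate noise,
quantifying the plate with the plate's own fixed calibrator reproduces the
expression matrix to numerical precision.

**What the generator does and does not show.** It reproduces the published
group *moments* exactly (within Monte-Carlo error), but moments are not the
whole distribution. At the published means and SDs the two groups overlap
far less than the published AUCs (0.63–0.70) imply — simulated univariate
AUCs at n = 34/33 are near 1 — which suggests the real per-subject
distributions were heavier-tailed or more contaminated than any
two-parameter family matched to those moments, or that the printed
dispersions understate the sampling variability. Passing tests on synthetic
cohorts therefore validate the *machinery* (quantification, summaries,
calls, ROC, panel building, stratification) and the printed-table
arithmetic, not the discriminative performance one should expect on real
saliva samples.

## Numerical choices and degenerate inputs

* Exact rank-sum enumeration only for pooled n ≤ 12 without ties; the
  corrected normal approximation otherwise; fully tied data return p = 1
  with a warning rather than an error.
* AUC ties receive half credit; AUC is invariant under strictly increasing
  score transforms and satisfies AUC + AUC(flipped labels) = 1 exactly
  (both tested).
* Bootstrap intervals use `quantile()` type 7 on the resampled AUCs;
  B ≥ 100 is enforced.
* Logistic fits stop at a log-likelihood change below 1e-8 or 100
  iterations; constant markers are input errors; separation is a warning,
  not an error.
* All seeded functions restore the caller's RNG state.

## Problem sizes used in validation

The shipped validation suite simulates at the study's size (34/33) for
structural and panel checks; 10,000 per group for moment matching and
null-fold-change checks; 100,000 controls for the call-rule specificity
limit; 500 replicate datasets with B = 500 for bootstrap coverage; and
1,000 random instances (n ≤ 50, ties injected) for the AUC/Mann-Whitney
identity. These sizes make Monte-Carlo error comfortably smaller than the
tolerances being asserted while keeping the full suite fast.

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(table2_defaults(seed = 7))
report <- run_pipeline(cohort, B = 1000, seed = 7,
                       pairs = list(c("CYP27A1", "SIAE"), c("MAOB", "NAB2")))
report$gene_summaries      # per-gene moments, fold change, p, cut-off
report$roc                 # univariate AUC/CI and Youden operating points
report$panels              # greedy panel sequence with AUCs
report$strata$`age<60`$roc # age-stratified re-analysis
write_report(report, "salivadx-report")
```
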