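---
title: "Methods: weighted genetic risk scoring for IVIG resistance"
author: "kdwgrs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted genetic risk scoring for IVIG resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdwgrs)
```

## The problem and the model

Intravenous immunoglobulin (IVIG) is the first-line therapy for Kawasaki
disease, but a minority of children remain febrile after a full course
and face a higher risk of coronary artery lesions. `kdwgrs` implements a
pipeline that predicts IVIG resistance *before* treatment from two
information sources: common germline SNPs and routine admission
laboratory values.

The genetic half is a weighted genetic risk score. For a panel of $n$
risk loci,
$$\mathrm{wGRS} = \sum_{k=1}^{n} w_k \, G_k,$$
where $G_k \in \{0, 1, 2\}$ counts copies of the *risk allele* of SNP $k$
(the allele with odds ratio above 1 in the discovery comparison) and
$w_k = \ln(\mathrm{OR}_k)$ is the allelic log odds ratio estimated when
the panel was selected. Weights are frozen into the panel at selection
time and never re-estimated downstream, so a panel file fully determines
the score of any genotyped sample.

The panel itself comes from a two-stage case-control design. Stage 1
(discovery) compares IVIG non-responders with responders; stage 2
(corroboration) compares non-responders with healthy controls. A SNP
becomes a candidate when it is common (MAF > 1 %) and nominally
significant ($P < 0.05$) in *both* stages, keyed by
(chromosome, position, ref, alt) rather than rsid; candidates are then
ranked by stage-1 $P$, cut at $P < 3\times10^{-3}$, and capped at
`k_max = 9` loci. Stage-1 drives the ranking because it targets the
clinical contrast of interest; stage 2 guards against loci that merely
distinguish patients from healthy children. A pairwise linkage-
disequilibrium check (squared Pearson correlation of dosage vectors,
flagged above $r^2 = 0.8$) is advisory by default — the panel of
independent biallelic SNPs is the modelling assumption, and the check
reports violations rather than silently repairing them.

The composite half augments the wGRS with laboratory variables that pass
a screen: a pooled-variance (Student's) two-sample $t$ test at
$\alpha = 0.05$ *and* less than 30 % missingness among non-responders.
The combined feature set feeds a bagged classification-tree model; the
per-sample score is the average of tree class probabilities, and the
headline evaluation uses out-of-bag (OOB) scores — each sample judged
only by trees whose bootstrap excluded it.

## Assumptions

* Genotypes are hard diploid calls; dosage uncertainty is out of scope.
* The allelic test treats the two alleles of a genotype as independent
  Bernoulli draws, which is exact under Hardy–Weinberg proportions.
* Chromosome-Y loci arrive as diploid calls from the upstream genotyper
  and are kept in diploid coding everywhere; `genotypeFrequencies()`
  exposes the sex-stratified view in which such loci should be judged.
* Laboratory values are conditionally normal given the response group;
  missingness is unrelated to the unobserved value (missing completely
  at random).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.01 | minimum minor allele frequency per scan (fraction) |
| `alpha_stage` | 0.05 | per-stage significance for candidacy |
| `p_final` | 3e-3 | stage-1 cut for panel membership |
| `k_max` | 9 | maximum panel size |
| `r2_max` | 0.8 | dosage-$r^2$ above which a pair is "strong LD" |
| `alpha_clinical` | 0.05 | clinical screen significance |
| `max_missing` | 0.30 | max missingness among non-responders (fraction) |
| `n_trees` | 100 | bagged trees in the composite model |

`k_max = 9` mirrors the size of the published panel while remaining a
parameter, since the nine loci's identities are not public. The LD
threshold quantifies "strong linkage disequilibrium", which the source
analysis reports only qualitatively.

**Why 100 trees rather than the conventional 25.** The classical bagging
default of 25 resamples is tuned for point prediction. Here the model is
*evaluated* through its out-of-bag scores: with $T$ trees a sample is
out-of-bag in about $0.368\,T$ of them, so at $T = 25$ each OOB score is
an average over ~9 trees — granularity ≈ 0.11, far too coarse to rank
330 patients on an ROC curve. At $T = 100$ each score averages ~37
trees. `n_trees` remains configurable.

**Why a class-stratified bootstrap.** With a 50/280 class imbalance a
plain bootstrap lets each resample's class proportion fluctuate
($\mathrm{sd} \approx 0.02$). A tree's probability output is a leaf
class proportion, so that fluctuation propagates to predictions — and
it *anti-correlates* with the out-of-bag samples' labels (a resample
rich in non-responders leaves relatively many non-responders out of
bag), biasing the OOB score of a null model below chance. Stratifying
the bootstrap within each class removes the fluctuation; the test
suite checks that null features then score inside the chance band.

## The synthetic cohort: what it emulates, what it does not

`cohortSpec()` defaults encode the study conditions: 50 IVIG
non-responders, 280 responders, 105 healthy controls; male fraction
211/330; ages (months) 30.5 ± 24.5 for non-responders and 34.3 ± 27.3
for responders. No age distribution is published for the healthy
controls, so they default to the responder parameters.

*Genotypes.* Fourteen planted risk SNPs carry the published baseline
ALT-allele frequencies (0.02–0.57) and allelic odds ratios (0.46–3.77);
`base_freq` is the frequency in responders, and the non-responder
frequency follows the closed form
$p' = \mathrm{OR}\,p/(1 + p(\mathrm{OR}-1))$. The odds ratio against
healthy controls is not published per SNP, so the default plants the
same OR in both comparisons (configurable per SNP via `or_control`) —
this makes both selection stages informative, matching the two-stage
design. Null background SNPs (default 500) share one frequency across
all groups, drawn uniformly from 0.05–0.5. All genotypes are
Hardy–Weinberg draws; panel SNPs are generated *independently*, so the
generator cannot exercise LD-driven redundancy (a deliberate non-goal;
`ldPruneCheck` is tested with explicitly duplicated dosage columns).

*Clinical table.* Each of 21 laboratory variables is normal within a
group with the published group means and the single published SD per
variable (used for both groups, as printed). Missingness is masked at
the published per-group percentages with a **fixed count**,
`round(rate * n)`, at random positions: the percentages describe the
observed cohort, and Bernoulli masking would let a variable documented
at 28 % missing cross the 30 % screening gate in nearly half of
simulated cohorts purely by masking noise. Variables are generated
independently — the source publishes only marginal moments — so the
generator understates the correlation structure of real laboratory
panels (e.g. haematocrit with haemoglobin). Only the two patient groups
receive clinical values. Normality itself is an assumption of the
generator, not a published property; heavy-tailed markers such as CK or
BNP are certainly not normal in reality, which limits how literally the
composite model's synthetic performance transfers.

A single seed drives a hierarchical stream (genotypes / clinical / sex /
age sub-seeds), so each sub-generator is independently reproducible and
a cohort is bit-identical across runs of the same seed.

Passing tests on these cohorts demonstrate that the *machinery* is
correct under the stated conditions; they cannot certify performance on
real sequencing data, where LD, batch effects, non-normal laboratory
distributions and informative missingness all exist.

## Numerical and procedural choices

* **2×2 association tests.** OR by cross-product; Haldane–Anscombe
  (+0.5 per cell) only when a zero cell occurs, and only for the OR/CI —
  never for the exact test. $P$ from the chi-square test *without*
  continuity correction, switching to Fisher's exact test when any
  expected cell count is below 5 (configurable). Yates' correction is
  deliberately avoided — it is conservative for 2×2 tables of this
  size, and the test suite verifies that the uncorrected test holds the
  nominal 0.05 type-I error over 2,000 simulated null cohorts.
* **Adjusted columns.** Sex/age adjustment is a logistic regression of
  case status on dosage plus the covariate(s); the reported $P$ is the
  dosage Wald test. Separation and non-convergence are flagged and the
  affected $P$ reported as absent, never fatal.
* **Ties and ranking.** Scan ordering: $P$ ascending, then
  $\lvert\ln\mathrm{OR}\rvert$ descending, then input order. Panel
  ordering adds genomic order as the last tie-break. An OR of exactly 1
  admits no risk allele and the locus is dropped from a panel with a
  warning (its weight would be zero).
* **Wilcoxon.** Midranks for ties; exact enumeration when both groups
  have ≤ 10 samples and no ties, otherwise the normal approximation
  with ±0.5 continuity correction and tie-corrected variance. Fully
  tied data sits at the null mean and reports $P = 1$.
* **ROC.** One operating point per distinct score, anchors at
  (sens, spec) = (0, 1) and (1, 0); trapezoidal AUC (equal to the
  tie-corrected concordance probability). Youden cutpoint ties resolve
  toward higher specificity, then lower threshold; a flat curve yields
  the degenerate extreme-threshold cutpoint with $J = 0$.
* **Missing data.** Association tests drop samples pairwise per SNP. A
  missing genotype at a panel SNP is imputed as twice the risk-allele
  frequency of the healthy-control group (frozen into the panel when
  selection sees the genotypes), keeping scores comparable across
  missingness patterns; `strict = TRUE` drops the sample instead.
  Composite features use frozen training medians at train and predict
  time.
* **Hard filter.** An absent quality annotation never fails its clause
  (rank-sum annotations are undefined without heterozygous calls, and
  removing such sites would discard clean homozygous sites).
* **Fever duration** passes the clinical screen in most simulated
  cohorts but is excluded from the composite feature set by default so
  that the model uses the six laboratory markers; `include_fever = TRUE`
  restores it.
* **Evaluation footing.** `evaluateModels()` reports the raw wGRS ROC
  (computed in-sample, as in the source analysis — its AUC inherits
  panel-selection optimism) *and* an equal-footing baseline: the same
  bagged model restricted to the wGRS feature, evaluated out-of-bag.
  Claims that laboratory variables add predictive value should compare
  `auc_composite` with `auc_wgrs_oob`; comparing an out-of-bag number
  against an in-sample one conflates model value with validation
  optimism. Resubstitution numbers are also reported, labelled as such.

## Problem sizes used by the test suite

The packaged tests run the default 435-sample cohort with 514 SNPs for
pipeline-level checks; 2,000 null cohorts for the type-I band; 500
replicates at $n = 500/500$ for effect recovery; 20 seeds at
$n = 500/500/500$ with 9 planted among 500 null SNPs for panel recall;
100 seeds for the clinical screen; and 20 seeds for the composite-gain
direction. These sizes were chosen so the full suite completes in a few
minutes while keeping Monte-Carlo error well inside each asserted band.

## Known limitations

* No LD-aware simulation or haplotype tests; no imputation of untyped
  SNPs; no Hardy–Weinberg QC exclusion (not part of the emulated
  design).
* The Kobayashi clinical score is consumed only as an optional
  precomputed column; its internal point thresholds are not
  implemented.
* Single-cohort evaluation only: no calibration analysis and no
  external validation, mirroring the emulated design. Out-of-bag
  evaluation is the only internal guard against optimism.
* The published 0.141 / 0.207 cutpoints are not numeric targets here:
  they depend on the unpublished cohort and on an unstated score
  transform, so the pipeline reports Youden cutpoints on its own score
  streams instead.
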