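---
title: "Multi-cohort CSF biomarker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort CSF biomarker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

csfsig implements a complete discovery workflow for cerebrospinal fluid
(CSF) proteomics case-control studies of Alzheimer's disease (AD): several
independent cohorts are measured with the same deep proteomic workflow and
their results intersected, so that disease-associated protein changes can
be separated from cohort-specific effects (a "rectangular" study design).
This vignette explains the statistical machinery, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
choices made where conventions were genuinely open.

## Biochemical case definition

Cohorts are harmonized with a uniform biochemical rule on ELISA
concentrations (ng/l): a sample is AD when t-tau exceeds 400 **and** either
Abeta1-42 is below 550 or the Abeta1-42/Abeta1-40 ratio is below 0.065.
All inequalities are strict, exactly as the rule is worded; a value sitting
on a cutoff classifies as non-AD. This boundary behaviour is a documented
choice (`clinical_thresholds()`), not an inference about intent. A missing
Abeta1-40 disables only the ratio branch — one cohort may lack that assay
and still be classifiable. Samples missing t-tau or Abeta1-42 are excluded
unless flagged `control_override`, the situation of young
emergency-department controls recruited without clinical chemistry, which
are retained as non-AD.

The Hulstaert index, `ab42 / (240 + 1.18 * t_tau)` with AD below 1, is
available as an alternative rule (`classify_cohort(rule = "hulstaert")`).

## Quality control

Proteins observed in fewer than 20 samples across the dataset are removed
(`filter_min_observations()`); intensities are then log10-transformed for
all statistics except coefficient-of-variation (CV) and correlation-map
analysis, which operate on the linear scale where CV is defined.
`compute_cv_report()` follows the replicate-plate convention: intra-plate
CV candidates are all 3-subsets of replicates within a plate; inter-plate
candidates take one replicate from each of three distinct plates (the
one-per-plate reading of "inter-plate combinations of three samples" — the
alternative, mixing two replicates of one day with one of another, is not
used). A candidate with fewer than two present values is excluded;
candidates with exactly two are retained. The protein CV is the median over
candidates, and the biological CV is the per-cohort CV across subjects,
median across cohorts. The 20% threshold in the report is the clinically
accepted assay-precision bound.

Z-scores (`zscore_proteins()`) are computed per protein within a stated
stratum (cohort or global) using the sample (n-1) standard deviation. A
protein with fewer than two present values, or zero variance, in a stratum
receives missing Z-scores rather than 0: a zero would inject fake
certainty into clustering and classification.

## Differential abundance

Per cohort and protein the two-group contrast is the unpaired pooled
(Student) t statistic on log10 intensities, and its moderated companion,
the SAM d statistic

$$d = \frac{\bar{x}_{AD} - \bar{x}_{ctrl}}{se_{pooled} + s_0},
\qquad s_0 = 0.001,$$

with `s0` applied on the log10 intensity scale. The pooled (rather than
Welch) form is used because the classical SAM denominator that `s0` was
designed to stabilize is the pooled standard error; the choice is exposed
through `two_sample_t()`/`sam_d()` for anyone wanting to swap it.

False discovery rates come from label permutations
(`permutation_qvalues()`): for each of B permutations (default 250;
exhaustive enumeration whenever the number of distinct assignments is at
most B) d is recomputed, and for each observed threshold the estimator

$$q_i = \frac{\mathrm{E}_{perm}\left[\#\{|d^{perm}| \ge |d_i|\}\right]}
{\#\{|d^{obs}| \ge |d_i|\}}$$

is clipped to [0, 1] and monotonized by a running minimum taken from the
least significant protein upward, so q never decreases as |d| decreases.
This SAM-style estimator is a reconstruction — the upstream tooling that
popularized it does not print its exact estimator or permutation count —
and is validated in the tests against exhaustive enumeration on small
designs and against its false-positive calibration on pure-null
simulations. Proteins with fewer than two present values in either group
are flagged untestable (`NA` statistics) and excluded from the FDR ranking;
missing values are otherwise handled by per-protein pairwise deletion,
mirroring the per-protein observation counting of the data.

## Cross-cohort signatures and overlap statistics

`cross_cohort_signature()` intersects the per-cohort tables: a protein
enters when significant (p or q below alpha) in every cohort, and is
*consistent* when its direction of change agrees — strictly — everywhere; a
delta of exactly 0 is consistent with nothing. The consistent subset is the
signature. Concordance between cohorts is quantified by the Pearson
correlation of log10 fold changes over co-significant consistent proteins.

Contingency analyses (enrichment of t-tau-correlated proteins in the
signature; overlap with external studies) use the two-sided Fisher exact
test with the sample odds ratio `(a d)/(b c)`. When a cell is zero the
Haldane 0.5 correction is applied and flagged. Confidence intervals for the
odds ratio (the Baptista-Pike construction used alongside such tables) are
out of scope; only the point odds ratio and p-value are consumed downstream.
External tables are matched by UniProt-style protein identifier first, gene
name as fallback — the same two-key matching that real cross-study
comparisons need when identifier conventions differ.

Signature heat maps cluster proteins on Euclidean distance of group-median
Z-scores and sample groups on correlation distance (1 - Pearson r), both
with average linkage. Average linkage is a choice (the upstream tool's
default is unstated) and is deterministic up to input order.

## Covariate association

`protein_covariate_correlation()` reports per-protein Pearson r against a
clinical covariate (t-tau, MMSE) with the analytic t-distribution p-value
and Benjamini-Hochberg q-values within cohort. Analytic rather than
permutation p-values are used here because the multiple-testing treatment
of correlation analyses in this field is conventionally BH. "Correlated
significantly" at the study level means p < 0.05 in *every* cohort with a
consistent sign (`multi_cohort_correlates()`); intersection, not pooling.

`covariate_adjusted_regression()` fits per-protein least squares of log10
intensity on AD status (or log10 t-tau), adjusting for age, sex and cohort,
with listwise deletion. Coefficients of continuous covariates are also
reported multiplied by the covariate's interquartile range so that binary
and continuous effect sizes are comparable; the IQR can be overridden
(e.g. a fixed 11 years for age) to reproduce a published scaling.

MMSE stratification puts the low-performance group strictly below the
cutoff (`mmse < cutoff`), matching the strictness convention used
everywhere else in the package.

## 1D annotation enrichment

`oned_enrichment()` ranks all n proteins ascending by a per-protein value
(typically the AD/non-AD log10 fold change; average ranks on ties) and
scores each annotation term as

$$s = \frac{2\,(\overline{rank}_{in} - (n+1)/2)}{n} \in (-1, 1),$$

positive when members concentrate at high values (AD-elevated). The
p-value is the two-sided Mann-Whitney test (exact for n <= 25, otherwise
the tie-corrected normal approximation), BH-adjusted across tested terms.
Terms with fewer than 10 or more than 100 members present in the dataset
are skipped: tiny and huge terms dominate enrichment lists without being
informative. The cross-cohort filter keeps terms below a per-cohort p
cutoff with a consistent sign of s; the default cutoff is 0.05, with 0.005
available — the two values both appear in the source conventions for this
analysis, so both presets are provided rather than guessing intent.

## Classification

The classification stage mirrors a two-step practice: first a single
axis-aligned decision tree (Gini impurity, exhaustive best splits) is used
as a transparent feature selector — `min_depth_for_full_training_accuracy()`
grows it just deep enough to classify the training data perfectly and
reports the features in tree order (root first, then by level and impurity
decrease). Because correlated proteins can swap positions,
`feature_rank_stability()` refits the tree (default 10,000 times; scale
down for quick runs) with shuffled sample order and randomized split
tie-breaking, reporting how often each protein occupies the root and the
second level. The tree is implemented in the package rather than delegated
because this resampling needs exact control of tie-breaking, which
off-the-shelf learners do not expose; deterministic mode breaks ties by
lowest feature index then lowest threshold. Zero-gain splits on impure
nodes are permitted so that XOR-like patterns, where no single split helps,
are still resolved at depth 2.

Generalization is then estimated with stratified k-fold cross-validation
(k = 6; stratified so small cohorts cannot lose a class from a training
fold — the plain shuffled split described in one place and the stratified
split described in another are reconciled toward stratified, and the
choice is switchable). Each training fold fits an XGBoost
binary-logistic model with early stopping (10 rounds, log-loss) on a
held-out 20% slice of the training fold; missing Z-scores are left as `NA`
for XGBoost, which handles them natively, and imputed to 0 for backends
that do not (`prepare_feature_table(impute_zero = )`). Every sample is in
the test set exactly once; the pooled test predictions at a probability
cutoff of 0.5 (a convention, fixed here) give the combined confusion
matrix, sensitivity, specificity and accuracy, and per-fold ROC curves give
the mean AUC. `iterative_feature_addition()` adds features in tree order
and selects the smallest count within `plateau_epsilon` (default 0.01 AUC)
of the best mean AUC.

## The synthetic-data generator

`default_paper_config()` fixes the study conditions: three cohorts with
group sizes 29/31 (AD / biochemical controls), 26/12/16 (AD / biochemical
controls / young overridden controls) and 33/26/24 (AD / depression /
subjective-cognitive-impairment controls) — 197 samples, 88 AD. Per
protein p and sample j,

$$\log_{10} I_{pj} = base_p + cohort_j + effect_p\,[AD_j] +
\textstyle\sum_k \lambda_{pk} f_{kj} + \varepsilon_{pj},$$

with `base_p ~ N(6, 1.2)` (about six orders of magnitude of dynamic
range), cohort offsets of ±0.05, per-sample noise sd 0.1 log10 units, two
latent-factor blocks (a neuronal-like block, loading 0.12, and a
blood-contamination block, loading 0.25), and a 40-protein signature: 39
proteins with fixed effects whose absolute fold changes run geometrically
from 1.25 to 1.352 (five of them reduced in AD), plus a MAPT-like protein
whose intensity tracks latent log10 t-tau with target Pearson r = 0.8,
giving it the largest effect (~0.24 log10, fold change ~1.7) — tau as the
top outlier. The 40 absolute fold changes have median 1.30. The narrow
range around 1.3 keeps the signature's median fold change at its
calibration anchor while leaving the MAPT-like marker clearly strongest,
which is what the rank-stability analysis assumes. Signature bases are
drawn from the upper abundance range (≥ ~6.2 log10): they emulate markers
reliably quantified in all cohorts, which any cross-cohort intersection
presupposes.

Missingness is abundance-driven, not MCAR: an entry drops out with
probability `plogis((m - log10 I)/s)`, midpoint m at the 20th percentile of
the base-abundance distribution and slope s = 0.5 — low-abundance proteins
vanish more often, reproducing the shape of real DIA completeness curves.
The logistic form itself is a modeling choice; no quantitative missingness
model is published for these data.

Clinical covariates are drawn per group (log10 t-tau N(2.845, 0.12) for AD
vs N(2.447, 0.12); Abeta1-42 420±90 vs 810±130; Abeta1-40 9800±1600 where
assayed; MMSE 22.7±4.5 vs 27.7±1.9 in the one cohort that scores it), with
availability masks per cohort and the overridden control subgroup kept
young (34±10 years) with chemistry missing. These separations make the
biochemical rule agree with the generating status for ~96% of samples —
deliberately imperfect, as real biochemical classifications are.

What the generator does **not** emulate: peptide-level quantification and
roll-up, normalization artefacts, batch drift within cohorts, age- or
sex-dependent proteome effects, heavy-tailed noise, and real protein
identities beyond the designated MAPT-like index. Passing tests on this
generator therefore demonstrate the statistical machinery recovers planted
structure under realistic dimensions, noise and missingness — not that the
pipeline's biological conclusions transfer to any particular real dataset.

## Numerical conventions and problem sizes

Sample standard deviations (n-1) everywhere; ties in ranks averaged;
degenerate statistics (zero pooled variance, sub-minimal group sizes)
yield `NA` rather than infinities and are excluded from rankings; the q
monotonization direction is from least to most significant; hierarchical
clustering tie-breaks follow input order. All randomized stages take
explicit seeds and are reproducible bit-for-bit.

The shipped tests exercise the full default conditions (1,500 proteins ×
197 samples, 250 permutations per cohort, 200 stability refits, 6-fold
XGBoost evaluation), chosen so the whole suite completes in a couple of
minutes on a single core while still running every stage at study scale.
The stability default of 10,000 refits is retained in `ml_config()` for
final analyses.

## Known limitations

- The permutation-q estimator is a faithful reconstruction of the SAM
  convention, not a byte-level reimplementation of any specific tool;
  q-values can differ from other implementations in tie handling.
- Fisher odds-ratio confidence intervals are not computed.
- The regression module fits one protein at a time; no shrinkage across
  proteins (limma-style moderation) is applied, matching the source
  analysis rather than improving on it.
- `cross_study_overlap()` assumes the external study reports a comparable
  log fold change; unit mismatches are the caller's responsibility.
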