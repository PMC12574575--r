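---
title: "Cell-type-resolved methylation-expression integration under allostatic load: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved methylation-expression integration under allostatic load: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylload)
```

## The scientific problem

Allostatic load (AL) summarizes multi-system physiological dysregulation —
cardiovascular, metabolic, neuroendocrine, lipid, oxidative-stress and
inflammatory markers — into a single composite score. Chronic dysregulation
plausibly leaves traces in DNA methylation and, through it, in gene
expression. Whole-blood methylation and transcriptome measurements, however,
are bulk signals: a beta value at a CpG is a cell-proportion-weighted
average over the constituent immune cell types, so both cell-composition
differences and genuine within-cell-type effects can create bulk
differences between high- and low-AL groups.

`methylload` implements the full analysis chain needed to separate these:
AL scoring and binary grouping, methylation and expression quality control,
in-silico cell sorting of both modalities for six blood cell types (CD8 T,
CD4 T, B, NK cells, neutrophils, monocytes), detection of *functional
CpG-gene pairs* — CpGs whose abnormal methylation state in a subset of the
high-AL group is associated with the expression of their linked gene — and
the downstream direction-of-regulation and gene-set over-representation
summaries. A synthetic-cohort generator with recorded ground truth makes
every stage testable without access to any cohort data.

## Allostatic-load scoring

Two variants are implemented:

* **Clinical-cutoff index** (`al_index_score()`): each of 14 biomarkers is
  dichotomized against a clinical threshold (sex-stratified where the
  threshold table provides it), 1 meaning the value lies *strictly* on the
  risk side. HDL cholesterol is the canonical below-threshold risk marker.
  The score is the plain sum, so it ranges from 0 to the number of
  configured markers; a sample missing any marker is flagged and excluded
  from grouping rather than imputed. Groups: `low` when score ≤ 2, `high`
  when > 2. Ties sit on the low side by construction of the strict
  inequality; the cutoff is configurable.
* **Absolute z-score sum** (`al_zscore()`): biomarkers are standardized
  against cohort (or supplied) reference statistics and the absolute
  z-scores are summed. The group cutoff is the cohort's third quartile,
  computed with the linear-interpolation quantile definition (type 7); the
  cutoff used is echoed in the output so alternative quantile conventions
  are auditable.

## Quality control

* `filter_probes()` removes sex-chromosome probes and blacklisted
  (cross-reactive/polymorphic) probes; a probe removable for both reasons
  is removed once and counted in both tallies.
* `infer_sex()` works from beta values alone: X-inactivation gives females
  intermediate chrX methylation, so a per-sample median chrX beta inside
  [0.35, 0.65] (configurable) is called female, anything outside male.
  Intensity-based sex inference is out of reach when the pipeline starts
  from beta matrices; this window rule is the beta-level analog.
  `drop_sex_mismatches()` removes samples whose predicted and reported sex
  disagree, leaving retained samples untouched.
* `quantile_normalize_stratified()` normalizes within probe-type strata
  (type I red / type I green / type II): each sample's values are mapped
  onto the stratum reference distribution, the element-wise mean of the
  reference samples' sorted values (all samples when no reference
  duplicates are designated). Descriptions of per-probe-type *and*
  per-methylation-status sub-distributions are not reconstructible as a
  per-probe stratification, so the stratification here is probe-type (and
  color channel) only; the "methylation status" axis is deliberately not
  implemented.
* `map_and_filter_genes()` drops expression rows with no gene symbol,
  collapses duplicate symbols (summing by default, preserving total
  signal; `first` and `maxmean` available), and drops genes with no
  observed value.

## Deconvolution

**Proportions.** `estimate_proportions()` solves, per sample, a
non-negative least-squares regression of the bulk expression over the
signature genes on an LM6-style gene-by-cell-type signature matrix, then
renormalizes the coefficients to the simplex. NNLS with renormalization is
deterministic and dependency-light; on low-noise mixtures it matches an
exhaustive simplex grid search to the grid resolution (this is asserted in
the tests). Support-vector-regression-based estimators differ mainly in
robustness to heavy feature noise, which the downstream contract (rows sum
to one, non-negative) does not depend on.

**Expression purification.** `purify_expression()` uses a two-step
constrained-regression scheme: per gene, NNLS across samples on the
proportion matrix yields shared cell-type profiles \(g_h\); each sample's
residual is then redistributed to cell types proportionally to their
contribution \(w_{ih} g_h\) (proportionally to \(w_{ih}\) when all
profiles are zero) and mapped back to the cell level, so the
proportion-weighted mixture of the purified signals reconstitutes the bulk
value exactly before clamping at zero. A cell type with zero proportion in
a sample receives no residual and reports the shared profile.

**Methylation tensor.** `fit_tca()` models each CpG independently as

$$x_{ij} \sim N\Big(\textstyle\sum_h w_{ih}\,(\mu_{hj} + c^{(1)}_i\gamma_{hj})
 + c^{(2)}_i \delta_j,\; \textstyle\sum_h w_{ih}^2 \sigma_{hj}^2 + \tau_j^2\Big),$$

with cell-level covariates \(c^{(1)}\) (entering once per cell type) and
global covariates \(c^{(2)}\). Fitting alternates an exact generalized
least-squares step for the mean parameters with bounded quasi-Newton
maximization over \((\sigma_{1j},\dots,\sigma_{Hj},\tau_j)\), stopping at a
relative log-likelihood change below `tol` (default 1e-6) or 100
alternations; both half-steps are ascent steps, so the log-likelihood is
non-decreasing (asserted per iteration in the tests). Cell fractions are
supplied externally (from expression) and are not refitted. The group
label is *not* a model covariate: the tensor is generated unconditionally
and the high/low comparison happens downstream in the association stage,
which keeps the detection hypothesis in one place. `tca_tensor()` then
returns the conditional expectation of each cell-level value given the
bulk observation,

$$\hat z_{hij} = \mu'_{hij} + \frac{w_{ih}\sigma_{hj}^2}
 {\sum_l w_{il}^2\sigma_{lj}^2 + \tau_j^2}\,
 \big(x_{ij} - c^{(2)}_i\delta_j - \textstyle\sum_l w_{il}\mu'_{lij}\big),$$

clipped to [0, 1].

Two practical properties of this estimator matter for interpretation.
First, \(\sigma\) and \(\tau\) are weakly separable — a common inflation of
all \(\sigma_{hj}\) mimics \(\tau_j\) — so \(\hat\tau_j\) often collapses
toward zero and measurement noise flows into the cell-level estimates.
Second, the per-sample shrink weights spread a subgroup effect of fixed
size into a smeared distribution at the cell level. Both effects limit
subset detection for low-abundance cell types; estimates for neutrophils
and CD8/CD4 T cells are considerably more informative than for NK cells at
the default composition.

**Reference-free components.** `refactor_components()` standardizes probes,
optionally regresses out technical covariates, scores each probe by the
error of its rank-\(k\) principal-subspace reconstruction, keeps the `t`
best-approximated sites and returns the first `k` principal components of
that submatrix as sample-level composition surrogates (defaults `k = 6`
matching the six cell types, `t = 500`). They are written as a diagnostic
output by the pipeline; they are not added to the model's covariates by
default because the proportion matrix already carries the composition
information in these analyses.

## Functional CpG-gene pairs

For each cell type, the association stage works on the purified
methylation and expression matrices.

**State calling.** `fit_beta_mixture()` fits 1-3 component beta mixtures
to the high-AL samples' beta values by EM. The M-step solves the weighted
maximum-likelihood equations for each beta component exactly (Newton
iteration on the digamma system in the weighted sufficient statistics
\(\overline{\log x}\), \(\overline{\log(1-x)}\)), so the EM log-likelihood
is monotone; three quantile-anchored starts per component count guard
against local optima, and the Bayesian information criterion selects the
component count. Deconvolved estimates clipped to [0, 1] produce genuine
point masses at the boundaries; these would otherwise be absorbed as
spurious high-concentration components, so a boundary carrying at least 2%
of the mass is modeled as a degenerate zero- or one-inflation component
and the beta mixture is fitted to the interior — the standard
zero/one-inflated treatment of methylation fractions.

`call_states()` labels a component *hyper* when its mean exceeds the
low-AL mean by more than `dm_threshold` (default 0.10 beta units) **and** a
one-sided rank-sum test of its member samples against all low-AL samples
is significant at `p_threshold` (default 0.05); *hypo* symmetrically;
members of unlabeled components are *normal*. Prevalences are the
fractions of high-AL samples in the hypo and hyper states.

**Expression test.** For each abnormal subset of at least
`max(5, 5% of high-AL)` samples, `pair_test()`/`run_mode()` compare that
subset's expression of the linked gene with the baseline — normal-state
high-AL samples pooled with all low-AL samples — by a one-sided rank-sum
test (normal approximation with tie correction; purified expression is
non-Gaussian by construction). The test side encodes the correlation mode:
in negative mode a hyper subset is tested for *lower* and a hypo subset
for *higher* expression; positive mode reverses both. All raw p-values of
one cell type and mode are adjusted jointly by Benjamini-Hochberg and a
pair is emitted when a state passes at `alpha` (default 0.05), with state
`dual` when both subsets pass. The multiple-testing scope (per cell type ×
mode) is this package's documented choice; pooling the baseline with the
normal-state subset keeps those samples informative and is configurable in
spirit by passing a restricted group vector.

`combine_modes()` concatenates negative- and positive-mode results with
the source mode retained.

## Direction of regulation

Per CpG: hypomethylated in negative mode, or hypermethylated in positive
mode, implies upregulation; the two remaining combinations imply
downregulation (`cpg_direction()`). Dual CpGs first resolve to the state
with the strictly greater prevalence (`resolve_dual()`); exact prevalence
ties are unresolvable under that rule and the CpG is excluded from
direction calling (logged) — the conservative reading of a rule that is
undefined at equality. Genes are upregulated only if all their CpG calls
(pooled over both modes within the cell type) are up, downregulated only
if all are down, otherwise *inconsistent* and excluded from downstream
proportions and enrichment (`gene_direction()`, `direction_calls()`).
`summarize_results()` tabulates pair counts, state proportions, direction
proportions and between-cell-type gene sharing, reporting both
per-cell-type occurrences and unique-gene tallies.

## Over-representation

`ora()` computes, per gene set, the upper-tail hypergeometric probability
of the observed overlap between a query list and the set within a stated
universe, with Benjamini-Hochberg adjustment across the sets of a
collection. The default universe for `stratified_enrichment()` is the set
of genes present in the expression matrix after preprocessing — the space
actually tested — and the adjustment is applied independently within each
namespace (e.g. a GO ontology or a pathway collection) of each (cell type
× direction) stratum. The reported `gene_ratio` is overlap over query size
(k/n); `k`, `n`, `K`, `N` are all stored so the alternative k/K convention
is derivable. No set-size filter is applied by default.

## The synthetic cohort generator

`generate_cohort()` produces the full input bundle plus a truth table. Its
defaults are the study conditions the package is tested under: 429
samples of which 126 (29.4%) are high-AL; six blood cell types with
Dirichlet(10, 8, 3, 2, 14, 5) mixing (neutrophils most abundant, NK
rarest); 2,000 CpGs and 1,500 genes with a 300-gene signature — deliberately
desk-scale so the full pipeline runs in minutes while keeping the sample
dimension realistic.

* **Methylomes**: per cell type, CpG means drawn from low (Beta(2,10)),
  mid (Beta(5,5)) and high (Beta(10,2)) regimes; 20% of CpGs are made
  cell-type discriminative with a guaranteed between-cell-type spread
  above 0.3. chrX probes get sex-dependent regimes (intermediate in
  females, predominantly low in males) to support the sex-inference test.
  Cell-level per-sample wobble is Gaussian with sd 0.02; bulk values are
  proportion-weighted mixtures plus truncated Gaussian noise (sd 0.03).
* **Transcriptomes**: log-normal gene means, distinct per-cell-type
  signature profiles, log-normal cell-level (sd 0.15) and bulk
  multiplicative (sd 0.10) noise. Bulk rows carry source identifiers with
  5% unmapped, exercising the gene-mapping stage.
* **Biomarkers**: 14 markers with fixed realistic population means and
  clinical-style cutoffs (HDL below-threshold, sex-stratified); high-AL
  samples receive 3-6 markers strictly past threshold, low-AL 0-2 with a
  skew toward 0-1, reproducing the repeated-low-integer score
  distribution. Group recovery by the index score is therefore exact.
* **Planted pairs**: 20 CpG-gene pairs allocated across cell types in the
  proportions such studies report for differentially methylated genes
  (CD8 T 37%, neutrophils 30%, B 13%, CD4 T 10%, monocytes 9%, NK ≈ 0),
  with a two-to-one lean toward negative-mode coupling. Each pair shifts a
  30% subset of the high-AL group by 0.3 beta units at the CpG (sign per
  state) in the target cell type, coupled to a 2-SD expression shift whose
  sign is chosen so the pair is detectable in the intended mode. Planted
  CpGs are chosen with headroom so the shift is not erased by truncation,
  and planted genes never collide with signature genes.

What the generator does **not** emulate: genomic coordinates and probe
chemistry, spatial correlation between CpGs, covariate effects (age, sex,
smoking) on methylation, batch structure, and non-monotone
methylation-expression relationships. Passing tests therefore demonstrate
the statistical machinery under the stated mixture model, not robustness
to those real-data features. Because no covariate effects are planted, the
packaged acceptance analyses run the model unadjusted — including inert
covariates (6 cell types × 3 covariates of pure noise) measurably costs
subset-detection power with estimated proportions; on real data, where the
covariates act on methylation, they belong in `c1`/`c2` and remain the
pipeline default.

## Numerical choices and degenerate inputs

* Beta values are clipped to [1e-4, 1-1e-4] inside the mixture EM;
  constant inputs return a one-component fit directly; EM stops at
  relative log-likelihood change 1e-6 or 100 iterations with a
  revert-and-stop guard against numerical decrease.
* The model fit initializes variances from the ordinary-least-squares
  residual split evenly between cell-level and residual terms; \(\tau\) is
  bounded below at 1e-6 to keep the working covariance positive.
* Quantile normalization interpolates tied (average) ranks linearly on the
  reference quantiles; strata with fewer than two probes pass through with
  a warning.
* NNLS proportion fits that return an all-zero coefficient vector (a
  pathological sample) fall back to uniform proportions with a warning.
* Dual-prevalence ties, empty mixture components, empty enrichment strata
  and empty GMT files are all handled by exclusion-with-logging rather
  than errors; hard errors are reserved for contract violations
  (duplicate identifiers, missing annotations, invalid configuration).

## Problem sizes used in the packaged checks

The test-suite and acceptance-script runs use: the full 429-sample design
for proportion recovery (100 CpGs — the proportion stage does not read the
methylome) and for association sensitivity (2,000 CpGs, 20 pairs in one
cell type at cell level); 10 null cohorts of 400 CpGs for the
false-positive rate; 20 replicates of 150-sample, 30-CpG, 3-cell-type
mixtures for shift localization; and one full standard-config cohort
(two in the acceptance script) for the end-to-end direction-recovery
check. These sizes are the package's chosen desk-scale study conditions;
the generator accepts larger dimensions unchanged.

## Known limitations

* Subset-level effects survive tensor deconvolution only for reasonably
  abundant cell types; at the default composition, NK-cell effects are
  essentially undetectable end to end, and overall end-to-end sensitivity
  is far below the cell-level sensitivity of the association stage. The
  direction of the effects that *are* detected is recovered reliably.
* The expression purification redistributes residuals proportionally to
  expected contributions; sample-specific effects in a cell type
  contributing little to a gene's bulk signal are attenuated accordingly.
* Only monotone methylation-expression coupling is modeled; dual
  methylation captures bidirectional methylation, not non-monotone
  expression response.
* The index AL score is a plain sum of its dichotomized markers (range 0
  to the marker count); published variants with compressed ranges
  aggregate dimensions in ways that are not reconstructible from a
  per-marker sum and are intentionally not imitated.
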