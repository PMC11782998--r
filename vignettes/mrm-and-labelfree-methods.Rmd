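---
title: "Targeted MRM quantitation and label-free differential expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted MRM quantitation and label-free differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmlfq)
```

mrmlfq implements the two computational arms of a knockout-mouse proteome
phenotyping workflow: an absolute-quantitation engine for targeted multiple
reaction monitoring (MRM) assays calibrated against stable isotope-labelled
internal standards (SILS), and a label-free differential-expression pipeline
for protein abundance matrices from knockout-vs-wild-type designs. Because
raw instrument data are not a software artifact, both arms are paired with
synthetic-data generators that reproduce the statistical structure each
stage assumes, so every stage is testable end to end.

## Peptide chemistry

All masses are monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water (18.01056 Da) plus modification deltas.
Carbamidomethylation (+57.02146 Da) is applied to every cysteine by
default, matching iodoacetamide alkylation; the heavy label is a
13C6,15N4 substitution on every arginine, a delta of
6 × 1.0033548 + 4 × 0.9970349 = 10.0083 Da. Ions are protonated at
1.00728 Da per charge: the precursor m/z is `(M + z·1.00728)/z`, a y-ion
is the C-terminal fragment (its residues plus the water), and a b-ion is
the N-terminal fragment without water — so the b- and y-neutrals of any
split sum to the peptide's neutral mass, with the single water carried by
the y fragment. Only y- and b-series ions are supported; average masses,
neutral losses and a/c/x/z ions are out of scope. Displayed m/z are
rounded half-up to one decimal, the convention of printed transition
lists; internal computation keeps full precision.

```{r transitions}
tt <- build_transition_table(
  list(peptide("GAFQQAAQILR"), peptide("LTCQGNAQWDGPEPR")),
  list(data.frame(type = "y", index = c(7, 6, 3), charge = 1),
       data.frame(type = "y", index = c(6, 5, 4), charge = 1)),
  precursor_charge = c(2, 3))
tt[, c("sequence", "precursor_mz_light", "precursor_mz_heavy",
       "fragment", "product_mz_light", "product_mz_heavy")]
```

## Ratio-to-heavy quantitation

The endogenous (light) amount in a sample is inferred from the ratio of
summed light to summed heavy fragment peak areas, against an external
calibration line fitted on a 1:2 serial-dilution ladder with a constant
heavy spike (default 50 fmol/µL).

Key choices:

* **Integration.** Baseline-subtracted trapezoidal area over the
  retention-time window; negative areas clip to zero. Light and heavy
  channels must co-elute within 0.05 min or a warning is raised.
* **Weighting.** The calibration line is fitted by 1/x-weighted least
  squares (x = nominal concentration) because the ladder spans three
  orders of magnitude and unweighted residuals would be dominated by the
  top levels; an unweighted fit is available by configuration.
* **Validation.** Back-calculated replicate concentrations are pooled
  per level across analyses; a level passes when the coefficient of
  variation is ≤ 15% and the relative error is within ±15% of nominal.
  Acceptance is applied to back-calculated concentrations (the relative
  error is only defined there), not raw ratios. The limit of detection
  is operationalised as the lowest passing level — a software-side
  definition, deliberately distinct from any instrument-specific LOD.
* **Identity.** The rdotp score — the normalised dot product between
  the light and heavy per-fragment intensity vectors — gates
  identification at ≥ 0.9, relaxed to ≥ 0.8 ("tentative") when the
  back-calculated concentration is within twice the LOD. The
  "near the LOD" region needed an explicit cutoff; 2 × LOD is this
  package's choice.
* **Units.** fmol/µL converts to fmol per 100 µg of digested protein by
  the reconstitution volume; the default 30 µL is the unique value
  consistent with the assay's two published conversion pairs
  (228/7.6 = 405/13.5 = 30). It is a logged, overridable parameter.
* **Ladder geometry.** The generator takes the point count and top
  concentration explicitly (defaults: 11 points from 1000 fmol/µL)
  rather than guessing between a stated point count and a stated bottom
  concentration that are mutually inconsistent under exact halving.
  The zero calibrator and blank are used for carryover checks only,
  never in the fit.

Group comparisons of quantified concentrations use the two-sample
Wilcoxon rank-sum test: exact by enumeration up to a combined n of 12
without ties, normal approximation with tie and continuity correction
otherwise.

## The label-free differential-expression model

The pipeline runs in a fixed order — filtering, zero imputation, TMM
normalisation, batch removal, precision weights, moderated test,
FDR/fold-change calling — with per-stage dimension logging.

**Filtering.** Proteins with mean intensity ≤ 0 in *every* condition are
removed; a protein absent in one genotype but present in the other is
kept, since deleting it would remove exactly the on/off biology a
knockout study looks for. Near-zero-variance proteins are then removed
when the most frequent value covers ≥ 90% of samples and the
most-frequent to second-most-frequent count ratio exceeds 95/5 (both
configurable).

**Imputation.** Each zero becomes half the smallest non-zero value *of
its own protein row* — the midpoint between zero and the next non-zero
value, resolved within protein so the result cannot depend on an
arbitrary sample ordering.

**Normalisation.** Trimmed mean of M-values: per sample, a weighted
trimmed mean of log2 ratios against a reference sample (the one whose
upper quartile is closest to the mean upper quartile), trimming 30% of
M-values and 5% of A-values two-sided with inverse-asymptotic-variance
weights. The normalised matrix divides each sample by its effective
size (library size × TMM factor) rescaled to geometric mean one, so
intensities keep their original magnitude.

**Batch removal.** Run-order blocks are formed by equal-sized
consecutive grouping of the acquisition order (default 3 blocks). Each
protein's log2 profile is decomposed by a *joint* two-way ANOVA into
condition effects, batch effects and residuals; the principal
components of the fitted batch submodel explaining ≥ 95% of its
variance are subtracted. Joint estimation matters: with an unbalanced
genotype-by-block layout, estimating batch from condition-adjusted
residuals leaves the confounded component inside the condition means
and biases every genotype fold change, whereas the joint fit removes
it. Condition effects are untouched by construction. Only the batch
submodel is filtered; residual variation is left alone, because
PCA-filtering residuals in small unbalanced designs risks absorbing
genotype-correlated variation.

**Precision weights and testing.** The corrected matrix enters a
voom-style transformation: log2 intensities with a 0.5 offset, and
per-observation inverse-variance weights from a lowess trend of
residual standard deviation against mean log intensity (intensities
are treated as count-like, reproducing the workflow this models). One
shared library size is used for every sample at this stage: the matrix
is already between-sample normalised, and re-normalising by raw column
totals — which a handful of high-abundance proteins dominate — would
re-inject per-sample noise into every fold change. The linear model
adjusts for age and sex; the genotype coefficient is tested with an
empirical-Bayes moderated t-statistic whose hyperparameters (prior
degrees of freedom d0, prior variance s0²) are estimated by moment
matching on the residual-variance distribution. Setting d0 = 0
recovers the ordinary t; d0 = ∞ pools completely. Significance
requires BH-adjusted p strictly below 0.05 *and* linear fold change
strictly above 1.5 (both thresholds configurable), with direction from
the sign of log2FC. Whether weights should be computed before or after
batch removal was an open choice; they are computed after, on the
corrected matrix, so the mean-variance trend reflects the data the
model actually sees.

## Enrichment and overlap

Over-representation uses the one-sided upper-tail hypergeometric test
with BH adjustment across sets. The background defaults to the proteins
quantified in the experiment, not a whole-genome universe: detection
bias makes the quantified set the honest reference population for
proteomics. The "% Members" statistic reported with each term is
100 × |query ∩ term| / |query| — the share of the *dysregulated set*
found in the term (the denominator is the query, not the term).
Cross-tissue overlap counts, for every protein differential anywhere,
the number of tissues in which it is differential, with ≥ k summaries
that are monotone by construction and invariant to input order.

## What the synthetic data emulate — and what they do not

`simulate_chromatogram()` produces Gaussian peaks on a uniform time
grid, co-eluting across light/heavy channels, with area proportional to
amount × fragment relative intensity, multiplicative log-normal noise
on areas (CV-parameterised, mean-one) and an additive Gaussian
baseline, clipped at zero. `simulate_abundance_matrix()` draws
log-normal protein intensities (baseline log2 means N(20, 2)), plants a
genotype log2FC of ±1.5 on a 10% subset, adds piecewise-constant
run-order batch offsets (default 0/+0.5/−0.5 on the log2 scale over
three blocks), optional age/sex covariate effects, and left-censors
intensities below a threshold (default 2^15) to zero — missingness tied
to low abundance, which is what the midpoint-imputation rule presumes.
The default design is 8 knockouts vs 10 wild types with genotypes
interleaved in run order, mirroring a realistic acquisition plan.

Real data differ in ways these generators do not attempt: peak tailing
and retention drift, interference that is correlated across fragments,
peptide-level missingness that is not purely intensity-driven,
heavier-tailed protein variances, and correlation between proteins.
Passing tests therefore demonstrate that the algorithms are correct
under their stated model, not that the model captures every property
of instrument output.

## Numerical choices and degenerate inputs

Rounding for display is half-up at one decimal. The trapezoid rule on
the default 0.004-min grid reproduces Gaussian areas to better than
0.1%. Calibration requires at least two distinct non-zero levels;
single-replicate levels report an undefined CV and are flagged
unevaluable rather than passed. All-zero intensity vectors make rdotp
undefined and raise an error distinct from a low score. Confounded
batch/condition designs are rejected, as are residual all-zero rows at
imputation (filtering must run first). Every simulator is
deterministic given its seed, and seeds are restored locally so
generation does not perturb the caller's random stream.

## Problem sizes used in the checks

The test suite exercises the pipeline at the study design (2000
proteins, 8 vs 10) for effect-recovery checks and at 1000 proteins
across 50 seeded replicates for the null false-discovery check; the
calibration properties use the default 11-point ladder in triplicate
across five analyses (165 injections). These sizes give Monte-Carlo
error comfortably below the thresholds being checked while keeping a
full run in tens of seconds.

## Known limitations

Quantitation assumes a linear response over the calibrated range and a
single interference-free integration window per transition; there is no
chromatographic alignment across runs, collision-energy optimisation or
retention-time scheduling. The batch model is piecewise-constant over
consecutive blocks and cannot represent smooth within-block drift.
Tissues are analysed separately; no joint multi-tissue model is fitted.
Enrichment requires a user-supplied gene-set collection (GMT) — no
annotation services are queried.
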