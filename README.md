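# mrmlfq

Proteome phenotyping of knockout mice by mass spectrometry, as a tested R
package: a targeted **MRM quantitation engine** (exact peptide/fragment m/z,
ratio-to-heavy calibration against stable isotope-labelled internal
standards, precision/accuracy validation, spectral-identity gating) and a
**label-free differential-expression pipeline** (filtering, midpoint zero
imputation, TMM normalisation, ANOVA-component batch removal, voom precision
weights, covariate-adjusted moderated t-tests, FDR/fold-change calling,
over-representation and cross-tissue overlap analysis). Synthetic-data
generators stand in for raw instrument data, so every stage runs and is
testable anywhere.

It is written for proteomics scientists who need a transparent, scriptable
version of this workflow — the parts usually buried in vendor software and
ad hoc scripts — with every threshold exposed and logged.

## The models in brief

**Targeted quantitation.** For a peptide with monoisotopic neutral mass
*M* = Σ residues + H₂O + modifications, the precursor at charge *z* is
(*M* + *z*·1.00728)/*z*; y-ions are C-terminal fragments (+H₂O), b-ions
N-terminal. A heavy standard carries ¹³C₆,¹⁵N₄ on each arginine
(+10.0083 Da). The endogenous amount follows from the light:heavy summed
fragment-area ratio *R* through a 1/x-weighted calibration line
*R* = a·c + b, back-calculated as c = (*R* − b)/a; each calibration level
must meet %CV ≤ 15 and |%RE| ≤ 15, and identity requires
rdotp = Σxᵢyᵢ/√(Σxᵢ²Σyᵢ²) ≥ 0.9 (0.8 near the detection limit).

**Differential expression.** After filtering and row-wise midpoint
imputation of zeros, samples are TMM-normalised (doubly trimmed weighted
mean of M-values), run-order batch components are removed by per-protein
two-way ANOVA plus PCA of the batch submodel (≥ 95% variance), and the
genotype effect is tested per protein by a moderated t-statistic
t̃ = β̂/(se·s̃), with posterior variance s̃² = (d₀s₀² + d s²)/(d₀ + d) from
empirical-Bayes moment matching, under a linear model adjusted for age and
sex with voom precision weights. Calls require BH-adjusted p < 0.05 and
linear fold change > 1.5. Enrichment is the one-sided hypergeometric test
against a quantified-protein universe, with "% Members" =
100·|query ∩ term|/|query|.

## Worked example

The `analysis/` directory holds the full narrative workflow
(`01_transition_table.R` … `04_enrichment_overlap.R`). In miniature:

```r
library(mrmlfq)

# the two-peptide assay table
tt <- build_transition_table(
  list(peptide("GAFQQAAQILR"), peptide("LTCQGNAQWDGPEPR")),
  list(data.frame(type = "y", index = c(7, 6, 3), charge = 1),
       data.frame(type = "y", index = c(6, 5, 4), charge = 1)),
  precursor_charge = c(2, 3))
tt[1, c("precursor_mz_light", "precursor_mz_heavy", "product_mz_light")]
#>   precursor_mz_light precursor_mz_heavy product_mz_light
#> 1              601.8              606.8            799.5

# calibrate, validate, quantify a noiseless 7.6 fmol/uL sample
ser <- simulate_calibration_series(n_replicates = 3, n_analyses = 5,
                                   noise_cv = 0.05, seed = 1)
cal <- process_calibration(ser)
cal$validation$lod
#> [1] 0.9765625
quantify_sample(simulate_chromatogram(7.6, 50, noise_cv = 0),
                cal$curves[[1]], lod = cal$validation$lod)
#> <quant_result> ratio 0.152, rdotp 1.000, 7.58 fmol/uL (227 fmol/100ug) [identified]

# differential expression on the synthetic 8-vs-10 knockout design
sim <- simulate_abundance_matrix(seed = 20260929)
res <- run_de_pipeline(sim$matrix, sim$metadata)
res$summary
#> total    up  down
#>   199   100    99
```

The quantitation line reads: a light:heavy area ratio of 0.152 against the
50 fmol/µL internal standard back-calculates to 7.58 fmol/µL (the 5%
calibration noise shifts the fitted line slightly off the true
7.6 fmol/µL), i.e. 227 fmol per 100 µg of digested protein at the 30 µL
reconstitution volume, with a perfect spectral match (rdotp 1.0). A
noiseless curve returns 7.6/228 exactly. The pipeline call
recovers 199 differential proteins on a matrix with 200 planted effects
(the per-stage log in `res$log` records what each stage removed).

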