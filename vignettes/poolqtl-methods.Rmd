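---
title: "Methods: pooled-frequency GWAS and multi-environment QTL consolidation"
author: "poolqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-frequency GWAS and multi-environment QTL consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poolqtl)
```

This vignette is the package's own account of its statistical machinery: the
models, the defaults and why they are set where they are, the numerical
choices, what the synthetic-data generator does and does not emulate, and the
known limitations — including an explicit power analysis of what a panel of
this size can and cannot detect.

## 1. The setting

A panel of hemp accessions (default 123) is genotyped as equimolar DNA pools
of 8 plants per accession, so each marker is observed as the *proportion of
the panel-major allele* in the pool — a value on the 1/16 grid blurred by
sequencing-depth noise — rather than a 0/1/2 genotype.  Markers sit on many
short scaffolds with no physical map.  Each accession is phenotyped in three
plots at each of three locations for beginning of flowering and full
flowering (in thermal time), the length of the vegetative period, and a
plot-level sex-determination score (1 = diecious, 2 = mixed, 3 = monecious).

## 2. Thermal-time phenology

`accumulate_thermal_time()` sums `max(0, T_d − base)` over daily mean
temperatures with base temperature 1 °C.  Two conventions deserve note:

* **Interval convention.** Accumulation runs over the *half-open* interval
  `[from, to)`: the start day contributes, the event day does not.  This
  makes accumulation exactly additive over abutting intervals
  (`[a,c) = [a,b) + [b,c)`), which the tests assert.  With daily increments
  of 10–20 °Cd the convention shifts values by less than one day's input.
* **Daily mean with a base-temperature clamp only.**  Hemp growth also has a
  reported optimum (29 °C) and ceiling (41 °C), but the flowering-time
  definitions used here reference only the base temperature, so no optimum
  curve is applied.  A configurable `ceiling_temp` cap is available and off
  by default.  Whether degree-days should use the daily mean or a min/max
  formula is not fixed by the data model; the daily mean is used and stated
  here.

Plots that never flowered keep missing flowering dates; their trait cells
stay missing (reported, never imputed with season-end values, which would
fabricate censored observations).  `aggregate_plots()` averages each trait
over the plots with non-missing values and averages the sex scores, so
`Sex_det` ranges in [1, 3] and hits the endpoints only when all plots agree.

## 3. SNP selection and the relationship matrix

`filter_snps()` applies the four classical pool-frequency filters — complete
call rate, biallelic frequency-sum ≥ 0.95, minor-allele frequency ≥ 2%, and
SD of the major-allele frequency ≥ 0.1 — in that fixed order.  The surviving
set is order-independent (each predicate is marginal); only the per-rule
removal counts in the report depend on the order, and filtering is
idempotent.  Ties in the "two major alleles" of the biallelic rule, and in
major-allele scoring, break by the fixed allele order A < C < G < T and are
logged.

`compute_kinship()` uses the VanRaden construction with the pooled frequency
plugged in as half a dosage: `x = 2f`, columns centered at `2p̄_j`, and
`K = ZZ' / (2 Σ p̄_j(1−p̄_j))`.  Keeping the 0–2 dosage scale means the same
code applies to individual genotypes (where the mean diagonal is ≈ 1; pooled
frequencies have smaller dispersion, so the raw diagonal is smaller — which
is why the phenotype generator normalizes its kinship, see §6).  Markers
fixed in the panel are excluded from both the product and the scaling sum.

`effective_marker_number()` implements the Li–Ji eigenvalue count
`Σ_i [1(λ_i ≥ 1) + (λ_i − ⌊λ_i⌋)]` on the marker correlation matrix,
computed per scaffold in windows of at most 200 markers (configurable) and
summed.  Windowing is what makes the method computable on hundreds of
thousands of markers; cross-scaffold correlation is ignored by construction,
which makes the estimate conservative (larger `M_eff`, stricter threshold).
Eigenvalues are rounded to 10 decimals before applying the formula: the
formula is discontinuous at integers, and perfectly collinear blocks
otherwise land on the wrong side of `floor()` by machine noise.  The
Bonferroni cut-off is `−log10(α / M_eff)`; `M_eff = 557` at α = 0.05 gives
4.047, and the default synthetic panel happens to have `M_eff ≈ 500`, i.e. a
comparable genome-wide stringency.

## 4. The kinship mixed model

`fit_null_model()` estimates `y = μ + u + e`, `u ~ N(0, σ_g²K)` by REML.  `K`
is eigendecomposed once; in the rotated basis the covariance is diagonal,
`σ_g²(λ_i + δ)` with `δ = σ_e²/σ_g²`, so the REML criterion is profiled over
`log10 δ` on a grid from −5 to 5 (0.1 spacing) and refined by bounded 1-D
optimization (tolerance 10⁻⁸, i.e. well inside the 10⁻⁶ contract).  The
criterion includes the `log|X'V⁻¹X| − log|X'X|` REML terms, so the value is
directly comparable to a textbook dense implementation — the tests hold the
eigen-path to a dense brute-force oracle at 10⁻⁶.  A δ estimate at the grid
boundary (h² → 1) is legitimate and occurs when the residual variance is not
separable from the polygenic bulk (see §7).

`association_scan()` keeps δ fixed at the null estimate and tests each marker
by weighted least squares in the rotated basis — the standard
population-parameters-previously-determined shortcut.  The per-marker
residual variance is re-estimated with n−2 degrees of freedom; the Wald
statistic `(α̂/SE)²` is referred to χ²(1) (the reference distribution is a
choice; at n ≈ 120 it is mildly anticonservative relative to F(1, n−2), by
≈ 0.2% at the 5% level).  An exact mode re-fitting δ per marker is available
behind `exact_per_marker = TRUE`; at these sample sizes it changes Wald
statistics by far less than their sampling noise and costs a full REML per
marker.  Markers constant after rotation are emitted with missing effects and
never significant.  Missing phenotypes are dropped case-wise per trait and
location, and each trait × location is analyzed independently; G×E is handled
downstream by consolidation, not by interaction terms.

The sex score is treated as a continuous response in the same model.  It is a
bounded, discrete scale, so its residuals are not Gaussian near the
endpoints; this is accepted deliberately to keep one model across traits.

`qq_diagnostic()` draws a seeded sample of 3,000 markers, pairs sorted
observed `−log10 p` with uniform order statistics, and reports the
genomic-inflation factor (median Wald over the χ²(1) median) and a
Kolmogorov–Smirnov statistic.  On the default structured null panel the
kinship-corrected scan is calibrated (λ_GC ≈ 1.0, empirical type-I ≈ 0.05)
while the uncorrected scan inflates to λ_GC ≈ 5.

## 5. MultiQTL models and cross-location consolidation

`forward_select()` reads "explains the largest phenotypic variance" as
*incremental* r² given the representatives already selected (marginal r² at
the first step) — the two readings coincide at step one, and a test asserts
the first pick equals the max-marginal-r² candidate.  Ties break by larger
Wald, then lexicographic marker id, making the procedure fully deterministic.
Collinear candidates (|r| ≥ 0.3 with the new representative, Pearson
correlation of major-allele-proportion vectors, absolute value since sign
carries no meaning for unphased frequencies) become members of that QTL and
leave candidacy — a first-assignment rule, so the output partitions the
significant set.  Selection stops only when candidates are exhausted; no
significance-based stop is applied.  The threshold 0.3 (~r² 0.1) is a fixed,
configurable constant (`analysis_config(r_threshold =)`), not re-derived from
the correlation–distance relationship of a reference genome.

`explained_variance()` regresses the trait on all representatives jointly and
reports the squared correlation of fitted versus observed values, computed as
1 − RSS/TSS (identical for least squares with an intercept, but numerically
stable when the fit is intercept-only).  Cumulative explained variance is
non-decreasing in selection order by construction.

`consolidate_across_locations()` correlates representative markers *between*
models from different locations, links pairs at |r| ≥ 0.3, and reports
connected components spanning ≥ 2 locations, named `QTL_<trait>_<k>` in a
deterministic order that does not depend on the input order of the models.
Components confined to one location are dropped: a cross-location QTL is by
definition environment-stable.  Correlations are computed on genotype
profiles; several same-location representatives may legitimately appear in
one component.  `pca_marker_profiles()` provides the companion visualization:
markers as observations, accessions as variables, column-centered SVD, scores
joined with `−log10 p` for the usual 3-D QTL landscape; component signs are
fixed by making the largest-magnitude loading positive.

## 6. The synthetic-data generator

`simulate_panel()` emulates the statistical structure of the real data, not
its sequences:

* **Population.** Ancestral allele frequencies per LD block are uniform on
  (0.2, 0.8) and dispersed into `n_subpops = 3` subpopulation frequencies by
  the Balding–Nichols construction at `fst = 0.15`.  A second
  Balding–Nichols layer (`accession_fst = 0.2`) gives every accession its
  own frequencies around its subpopulation's: accessions in a diversity
  panel are distinct cultivars and landraces, not random samples of one
  population, and without this layer the pooled frequencies would carry no
  heritable accession-level signal beyond pool-sampling noise.
* **LD.** Markers within a block (default block length 8 kb on scaffolds
  with 4–10 markers) copy one latent haplotype per pool haplotype, broken
  per marker with probability 0.05, giving within-block |r| ≈ 0.9 and
  cross-block |r| near the structure baseline.  This is a block-copy model,
  deliberately simpler than a coalescent: it is sufficient to exercise the
  r ≥ 0.3 clustering and the `M_eff` machinery.
* **Pooling and reads.** Each accession pools 16 haplotypes; the observed
  frequency is a binomial read sample at Poisson-distributed depth (mean
  30×, the scale implied by ~2 Gbp of reduced-representation data per
  sample; `Inf` disables read noise).  Without read noise, frequencies lie
  exactly on the 1/16 grid.
* **Phenotypes.** Trait genetic values are planted-QTL effects on the
  2×frequency dosage of the *noise-free* pool frequencies plus a polygenic
  draw with covariance proportional to the true-frequency kinship,
  normalized to unit mean diagonal.  Polygenic draws are orthogonalized
  against the planted dosages and rescaled to their target variance: with
  three subpopulations the structure axes hold half the variance in ~2
  effective degrees of freedom, so raw draws would make realized
  heritability and planted variance fractions extremely noisy; after this
  stabilization both are exact per panel.  Between-location polygenic
  correlation is `env_genetic_correlation = 0.8`; location-private QTLs act
  in one location only.  Plot noise is sized so the accession-by-location
  mean attains the target heritability (defaults 0.93–0.95 across traits,
  matching the high broad-sense heritabilities reported for such panels).
* **Planted-QTL placement.** Effects are planted on the highest
  *within-subpopulation*-variance marker of unused LD blocks, requiring
  pairwise |r| ≤ 0.15 among the chosen markers.  A causal variant whose
  variance is mostly between-subpopulation is statistically inseparable from
  the structure that the kinship term absorbs — planting there would make
  the truth unrecoverable by *any* structure-corrected method — and the
  near-orthogonality keeps the planted variance fractions from leaking into
  each other.
* **Observables.** Flowering genetic values map to °Cd scales (FL_Begin
  420 ± 60, FL_Full 620 ± 70 °Cd) and are inverted through each location's
  simulated temperature accumulation into calendar dates (erroring if a
  value exceeds the season's accumulable thermal time); `FL_Full` is clamped
  to be at least `FL_Begin`, and `VEG` emerges from the dates rather than
  being generated (so planted effects cannot target it directly).  Sex
  scores cut a standardized plot-level liability at ±1 SD into {1, 2, 3}.
* **Determinism.** One RNG substream per (stage, seed) — marker map,
  haplotypes, read noise, phenotypes, temperatures — so adding read noise
  does not perturb phenotype draws, and equal seeds give byte-identical
  output.

What the generator does **not** emulate: coalescent-accurate LD decay,
sequencing reads, selfing/crossing structure, sex chromosomes, photoperiod
response, or any real hemp sequence.  Tests passing on this generator
therefore validate the *statistical machinery* — calibration, oracle
equality, recovery of identifiable planted truth — not performance on real
RAD-seq data.

## 7. Power: what this design can and cannot detect

A closed-form bound worth stating explicitly.  A QTL explaining a fraction
r² of the phenotypic variance gives an (oracle) Wald noncentrality of about
`n·r²/(1−r²)`; at the default panel (n = 123) an 8%-variance QTL yields
≈ 10.7.  The genome-wide cut-off of `−log10 p ≈ 4` (M_eff ≈ 500) corresponds
to a critical χ² of 16.6, so even a perfectly calibrated test of the causal
marker itself — no structure, no pooling or read noise — detects such a QTL
with probability ≈ 0.33 per location; the realized pipeline power matches
(~0.3).  Requiring detection in ≥ 2 of 3 locations for cross-location
consolidation compounds this, so reliably recovering several independent
8% QTLs per panel would need roughly twice the noncentrality (n ≈ 280, or
~18% QTLs).  The structured polygenic background does not rescue this: with
three subpopulations the kinship absorbs the structure axes, but the
within-subpopulation polygenic variance lies in the same eigenspace as any
identifiable marker signal and is irreducible by mixed-model weighting.  The
package reports recovery honestly (see `scripts/acceptance.R`); the worked
example in the README uses a 15% QTL, which is comfortably detectable.

## 8. Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: panels of
25–123 accessions, 300–2,000 markers, 3 locations, 5 replicate seeds for
calibration (5 × 2,000 = 10,000 null tests) and recovery studies.  Key
numerical choices collected in one place: REML grid −5..5 (log10 δ, step
0.1) plus bounded refinement at 10⁻⁸; kinship symmetrized and accepted PSD
down to −10⁻⁸; Li–Ji eigenvalues clamped at 0 and rounded to 10 decimals;
explained variance as 1 − RSS/TSS clamped to [0, 1]; forward-selection ties
by Wald then marker id; motif search is Hamming-only (no gaps) with `N`
never matching, 1-based inclusive coordinates, and an optional
`table1_style` writer emitting `end = start + length` for comparability with
coordinate tables using that convention.
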