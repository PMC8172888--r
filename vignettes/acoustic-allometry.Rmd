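---
title: "Comparative analysis of acoustic signal frequency with phylofreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of acoustic signal frequency with phylofreq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofreq)
```

## The scientific problem

Across species, the sound frequency of acoustic signals scales negatively
with body size: larger animals produce and radiate low frequencies more
efficiently. Habitat may add a second deterministic pressure (dense
vegetation attenuates high frequencies), and different signal classes —
sexually selected advertisement songs versus general-purpose contact
calls — may differ both in how tightly frequency tracks the phylogeny
(phylogenetic signal) and in how strong the allometry is. phylofreq
implements the statistical machinery needed to ask these questions on a
species-level trait table and a sample of phylogenies:

1. Pagel's-λ phylogenetic signal per trait;
2. λ-optimized PGLS regressions of peak frequency on body mass, habitat
   and song duration;
3. AIC-weighted averaging of every fitted quantity across a sample of
   trees, to propagate phylogenetic uncertainty;
4. a Z test comparing standardized allometric slopes between signal
   classes;
5. a heteroscedasticity test regressing absolute averaged residuals on a
   predictor;
6. one-way-ANOVA intraclass-correlation repeatability of repeated
   acoustic measurements; and
7. peak-frequency extraction from audio recordings.

## The model

### PGLS with Pagel's λ

Under Brownian trait evolution on a rooted tree with branch lengths, tip
values are multivariate normal with covariance proportional to `C`, whose
diagonal holds root-to-tip path lengths and whose off-diagonals hold the
shared path length of each pair (`phylo_vcv()`). Pagel's λ multiplies the
off-diagonals by a factor in [0, 1] (`lambda_transform()`), interpolating
between phylogenetic independence (λ = 0) and pure Brownian structure
(λ = 1). The regression model is

y = Xβ + ε,  ε ~ N(0, σ² C(λ)).

For fixed λ the GLS estimates are β̂ = (X'C⁻¹X)⁻¹X'C⁻¹y with profiled ML
variance σ̂² = e'C⁻¹e/n and log-likelihood
−½[n log(2πσ̂²) + log|C(λ)| + n]. λ is estimated by maximizing this
profile over [0, 1]; the upper bound is fixed at 1 because beyond it
C(λ) can lose positive definiteness.

Numerically, the package factors C(λ) = D^{1/2}(λC* + (1−λ)I)D^{1/2}
with D the diagonal of C and C* the corresponding correlation matrix.
One symmetric eigendecomposition of C* per tree then turns every λ into
a weighted least-squares problem with weights λe_i + (1 − λ), so the
whole profile costs one decomposition plus trivially cheap per-λ
solves (assembled from weighted cross-product sufficient statistics).
This factorization is valid for any tree; no ultrametricity is assumed,
which matters because jittered tree samples are not ultrametric.
`pgls_prepare()` exposes the per-tree decomposition so that several
models fitted on the same species set share it.

The search uses a coarse grid (step 0.01) followed by local refinement
with `optimize()`, guarding against local optima that a purely local
search could fall into. A profile that is flat to within 1e-8 (a star
phylogeny: all off-diagonals zero) returns λ = 0 with a `profile_flat`
flag — λ is unidentifiable there and 0 is the declared tie-break.

Conventions, all switchable where noted:

* ML, not REML, throughout: AIC comparison of the same model across
  trees requires a consistent full likelihood. AIC counts the
  regression coefficients plus σ² and λ as free parameters.
* Standard errors use the unbiased residual-variance denominator
  (n − k), the convention in GLS software; `se_method = "ml"` switches
  to the ML denominator.
* Per-coefficient P values are two-tailed from a t reference with
  n − k degrees of freedom.
* Rows are deleted per model (each model uses every species with
  complete data for its own variables), so song and call models can
  legitimately use different species counts.
* Body mass and song duration are modelled on the log10 scale; peak
  frequency is left untransformed by default (cross-species frequency
  distributions are typically already bell-shaped), with
  `log10_frequency = TRUE` available.

### Averaging across a tree sample

Phylogenies are uncertain; analyses therefore run on a sample of trees
and combine results with Akaike weights computed from each tree's model
AIC, w_i ∝ exp(−Δᵢ/2) (`aic_weights()`). Every reported quantity —
coefficients, standard errors, standardized slopes, λ, per-species
residuals — is the weight-averaged value across trees
(`average_fits()`). Two open choices were resolved as follows:

* Standard errors are averaged directly (plain weighted mean); the
  unconditional-variance alternative, which adds the between-tree
  spread of the estimates, is available via
  `se_average = "unconditional"`.
* λ is averaged on its natural scale (no logit transform).
* P values are not averaged; they are recomputed from the averaged
  estimate and standard error on a t reference with the averaged n.

### Standardized slopes and their comparison

Slopes are standardized as β_st = β·sd(x)/sd(y) so they are comparable
across responses measured in different units; standard errors scale by
the same factor. Two standardized slopes estimated on independent data
are compared with Z = (b₁ − b₂)/√(se₁² + se₂²) against a standard
normal (`compare_slopes()`). With the species counts this design targets
(hundreds of species) the normal reference is appropriate; a Welch-t
reference is available when degrees of freedom are supplied.

### Absolute-residual regression

To ask whether a predictor is associated with larger *non-directional*
deviations from the fitted optimum, per-species residuals are first
weight-averaged across trees, then their absolute values are regressed
on the predictor with a fresh λ-PGLS on every tree and averaged again
(`abs_residual_regression()`). The order — average first, take the
absolute value second — changes results and is therefore fixed and
stated.

### Repeatability

Within-species consistency of repeated measurements is the intraclass
correlation from a one-way ANOVA with the unbalanced-design correction
n₀ = (N − Σnᵢ²/N)/(a − 1), s²_A = (MS_A − MS_W)/n₀,
R = s²_A/(s²_A + MS_W) (`repeatability()`). Species with a single
recording are retained (they contribute to the among-group bookkeeping);
a negative estimate is reported as computed, flagged rather than
truncated, so that the diagnostic information is not lost.

### Peak frequency

`peak_frequency()` implements "the frequency with the highest cumulative
sound amplitude": magnitude spectra of successive Hann-windowed frames
(1024 samples, 50% overlap by default) are accumulated over the
annotated segment and the maximal bin inside a search band (0.2–12 kHz
by default) is returned. All settings are arguments; magnitude rather
than power is accumulated by default (switchable). Ties within a 1e-9
relative tolerance break to the lowest frequency for determinism. The
measurement is invariant to global amplitude scaling. Durations come
from segment annotations only — there is deliberately no automatic onset
detection. A minimal PCM WAV reader/writer (`read_wav()`, `write_wav()`)
covers file I/O; stereo input is averaged to mono.

## The synthetic-data generator

`sim_study()` generates the full data layout the pipeline consumes, with
the statistical structure the analysis assumes:

* an ultrametric pure-birth tree rescaled to unit depth
  (`sim_yule_tree()`), default 591 species;
* a pseudo-posterior of trees made by multiplying each branch length by
  lognormal noise with mean 1 and CV 0.2 (`jitter_trees()`), topology
  fixed — a deliberate simplification of real posterior samples, which
  also vary topologically; it is sufficient to exercise AIC weighting
  but cannot probe sensitivity to topological error;
* traits drawn from N(μ, σ²C(λ)) (`sim_trait()`): log10 body mass with
  λ = 0.9 (root 1.3 ≈ 20 g, tip SD ≈ 0.45), log10 song duration with
  λ = 0.45 (root 0.5 ≈ 3 s, tip SD 0.3), and a λ = 0.75 latent habitat
  trait squashed through a logistic map to a proportion in [0, 1] —
  echoing the high empirical signal of habitat while respecting its
  scale;
* peak frequencies (kHz) built as intercept + slope·log10(mass) +
  habitat effect + a λ-structured residual: song slope −0.5 with λ = 0.3
  residuals, call slope −0.35 with λ = 0.65 residuals, habitat effect 0
  (the planted null), residual SD 0.4 — chosen so the standardized mass
  slopes land near −0.5 (song) and −0.35 (call), the regime the analysis
  targets;
* calls present for ~85% of species (505/591), mirroring incomplete call
  coverage;
* three noisy recordings per species and class, with measurement SDs
  (0.175 kHz for frequency, 0.2 log10 units for duration) planted so
  that frequency repeatability is ≈ 0.87 and duration repeatability
  ≈ 0.7; the trait table uses the measurement means for acoustic traits
  and exact values for mass and habitat (which a real study takes from
  the literature rather than measures).

All generators are deterministic given `seed` and leave the caller's RNG
stream untouched. What passing tests on these data do *not* show:
robustness to topological tree error, to non-Brownian evolution (OU,
rate shifts), to measurement error on predictors, or to taxonomic
name mismatch beyond exact matching.

## Verification strategy and problem sizes

The suite checks every layer against an independent route: the
covariance builder against brute-force shared-edge enumeration; the GLS
solver against Cholesky-whitening-plus-OLS; the λ optimizer against an
exhaustive 1e-4 grid and against `phytools::phylosig()`; the ICC against
base-R `aov()`; λ = 1 simulation against recursive branch-increment
Brownian motion (Kolmogorov–Smirnov). End-to-end, parameter recovery
runs 100 replicates of a 200-species study over 50 jittered trees
(recovering λ = 0.9 on mass and the planted −0.5 slope, with the null
habitat effect near zero), and the two hypothesis tests are calibrated
under planted nulls over 500 replicates of 100-species studies,
holding their nominal 5% size. These sizes were chosen to make
Monte-Carlo error small relative to the assertion bands while keeping a
full run comfortably fast on one core.

## Known limitations

* Tree uncertainty is emulated by branch-length jitter only.
* The normal reference of the slope-comparison test is slightly
  anticonservative at small n; use the Welch option there.
* The absolute-value response of the heteroscedasticity regression is
  folded-normal rather than normal; its size is verified by simulation
  rather than assumed.
* No OU or measurement-error models; λ is the only covariance dial.
* Species matching between table and trees is exact string matching;
  taxonomic reconciliation is out of scope.
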