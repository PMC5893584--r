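---
title: "Methods: longitudinal urinary organic-acid analysis with uromet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal urinary organic-acid analysis with uromet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromet)
```

`uromet` analyses paired crossover intervention studies of urinary organic
acids: each subject contributes five hourly samples (0–4 h) under each of two
interventions, and every sample is a vector of metabolite concentrations.
This vignette documents the statistical model behind each stage, the
defaults and why they were chosen, what the synthetic generator does and does
not emulate, and the numerical decisions a maintainer should know about.

## Data model and preprocessing

A `metab_profile` couples a sample-metadata tibble (subject, intervention,
hour, analytical role, batch, injection order, creatinine) to a samples ×
metabolites concentration matrix, with a forward-only transform state
(`raw → imputed → log → scaled`) so a matrix can never be log-transformed
twice or fed to a latent model untransformed.

**Creatinine normalization.** Urine concentration varies with water intake,
so raw μmol/L values are divided by the sample's creatinine (mmol/L), giving
μmol metabolite/mmol creatinine. Every injection — experimental, pooled QC,
repeat — is normalized by its own creatinine. The operation is exactly
invertible, which the tests exploit.

**Zero treatment.** GC–MS non-detects arrive as exact zeros. Each zero is
replaced by half the smallest positive value of that metabolite across
experimental samples: the common metabolomics convention that keeps the log
transform defined while preserving "below everything observed". Metabolites
that are zero everywhere carry no information and are dropped with a warning
(mechanically mimicking panel reduction during curation). Half-minimum was
chosen over model-based imputation because at n = 12 per cell there is too
little replication to fit a censoring model per metabolite.

**Transform and scaling.** Natural log, then per-metabolite centering with
one of three scalings: `auto` (unit variance; the default, because VIP and
loadings then compare metabolites on a common scale across four orders of
magnitude of concentration), `pareto` (divides by the square root of the SD;
kept configurable because some practitioners prefer its compromise between
raw and auto scaling), or `none`. The per-column mean and divisor are
retained so held-out samples project into the training space exactly. QC and
repeat injections never drive the scaling parameters — they are diagnostics,
not observations.

**Contrast-local scaling.** Two-group models (PCA/PLS-DA of 0 h vs. t h) are
fitted on data re-scaled *within the contrast subset*. A metabolite whose
response peaks late would otherwise have its 0-vs-1 h contrast standardized
against variance it only exhibits at hours 2–4, shrinking its weight in a
model that never sees those hours. Scaling within the modelled subset is the
standard chemometrics practice of scaling the matrix you decompose.

**QC repeatability.** Per batch, the first five pooled-QC injections
condition the column and are excluded; the RSD across the remaining QC
injections estimates analytical precision per metabolite, and each repeat
injection is compared to its original as an absolute percent difference.
Batches with fewer than two usable QCs are marked unavailable rather than
reported from a single point.

## PCA, PLS-DA and VIP

PCA is the thin SVD of the centered matrix; explained fractions are squared
singular values over the total sum of squares. Component signs are fixed so
the largest-magnitude loading entry is positive — a pure reporting convention
that makes runs bit-reproducible.

PLS-DA uses NIPALS on a centered 0/1 class indicator (the chemometrics
reference algorithm): per component, the weight vector is the normalized
covariance between the deflated X and the deflated response, and both are
deflated by the extracted score. The response variance explained per
component, SSY_a = q_a² t_a't_a, feeds the VIP:

$$\mathrm{VIP}_j = \sqrt{\; p \cdot \frac{\sum_a \mathrm{SSY}_a\, (w_{ja}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}\;}$$

with p the number of variables. This is the standard weight-based definition;
mean(VIP²) = 1 by construction, so VIP ≥ 1 flags variables contributing more
than average. Selection models default to 3 components and score plots to 2;
cross-validated component selection is deliberately out of scope, so k is a
visible, documented knob rather than a hidden optimisation.

The multilevel split (`multilevel_split()`) separates each sample into its
subject's mean profile (between part) and the deviation from it (within
part); the two parts reconstruct the input exactly. Fitting the latent models
to the within part is the paired analogue of the unpaired fits.

## ASCA

The centered matrix is partitioned by the design factors — time and
participant, main effects only — exactly as an ANOVA partitions univariate
variation: the effect matrix of a factor assigns each sample its factor-level
mean profile (after removing the grand mean), and the residual is what no
factor explains. Reconstruction is exact by construction, and in a balanced
design the effect matrices of different factors are orthogonal, so the total
sum of squares splits additively. Unbalanced designs still decompose but are
flagged, and orthogonality is not asserted.

Each effect matrix is summarized by PCA (simultaneous component analysis);
its rank is at most levels − 1, which bounds k. Because an effect matrix is
constant within a level, within-level scatter comes from projecting the
residual onto the effect loadings; the 95% centroid ellipsoid is the
chi-square contour of that scatter's covariance divided by the level's sample
count. Residual-augmented *scores* are off by default (pure effect-matrix
SCA) and available behind `augment = TRUE` — both variants are implemented
because published score plots do not always state which was used.

Significance of a factor uses a permutation test with the factor's sum of
squares as statistic. Time labels are permuted within subject (and vice
versa), respecting the nesting of repeated measures so exchangeability under
the null is honest; p = (1 + #{null ≥ observed}) / (n_perm + 1) with 199
permutations by default.

## Unfolded PCA, trajectories and bi-plot ranking

The cases × time × metabolite tensor is unfolded batch-wise into a cases ×
(metabolite·time) matrix: one row per case (subject within the analysed arm),
columns ordered metabolite-major with one block per hour. PCA is fitted to
the column-centered unfolded matrix, so model scores describe between-case
variation and vanish when cases are identical.

Per-time points are **block scores**: the projection of a case's time-t
sub-profile onto the time-t block of the loadings. The centered block scores
of a case sum exactly to its model score (block-score additivity — an
algebraic identity of splitting the inner product). Trajectory points are
computed from the *uncentered* (per-metabolite preprocessed) values, so the
per-time centroid — the mean of the case points at that hour — carries the
mean time course, while the scatter around it carries inter-individual
variation; 90% chi-square ellipsoids summarize that scatter per hour. This
block-score construction is this package's explicit design choice for
reconciling a case-rows unfolding with per-time centroids and per-case
trajectories in one coherent object. One consequence worth stating: the
average of the per-time centroids is only approximately at the origin,
because loadings differ across time blocks, so the per-metabolite zero-sum of
the preprocessed data does not transfer exactly to the projections; the
package asserts the identities that do hold exactly (additivity, centroid =
mean of points, zero scores under zero between-case variation) and does not
claim that one. Note also that a response that is perfectly homogeneous
across cases lives entirely in the column means: case-centered loadings
cannot align with it, and the per-time centroids will reflect it only insofar
as between-case variation correlates with it — which in real cohorts it does.

Bi-plot ranking orders metabolites by the sum of squared loadings on the
first two components (optionally within one time block), descending, with
lexicographic tie-breaks; the top seven are reported by default, matching the
usual bi-plot legibility limit.

## Univariate statistics, selection, correlation, power

**Signed fold change** is the ratio of arithmetic means of
creatinine-normalized (untransformed) concentrations, reported as +ratio when
≥ 1 and −1/ratio otherwise so that |FC| is symmetric for rises and falls.
Means are taken on the concentration scale, not the log scale, because that
is how per-time summary tables are conventionally printed and how reported
fold-change columns reproduce from reported means. Output tables round FC to
one decimal; full precision is retained internally.

**Wilcoxon signed-rank test.** Zero differences are dropped, ties among
absolute differences get mid-ranks, and for n ≤ 25 the two-sided p comes from
the exact permutation distribution of the statistic conditional on the
observed ranks — computed by convolution over doubled ranks (doubling keeps
mid-ranks integral), which is identical to enumerating all 2ⁿ sign
assignments but costs O(n · Σranks). Above n = 25 the normal approximation
with tie and continuity correction takes over. At n = 12 the smallest
achievable two-sided p is 2/4096 ≈ 0.000488, and the test's true size at a
0.05 gate is the attained level 0.0425 — discreteness every user of exact
tests at small n should expect; the calibration tests check against that
attained level rather than pretending the discrete test rejects at exactly
5%.

**Selection** is the conjunction VIP ≥ 1.0 ∧ p ≤ 0.05 ∧ |FC| ≥ 1.5 at the
0 vs 1 h contrast in the alcohol arm, reported one record per metabolite with
per-time means/SDs and the 0 vs 4 h statistics alongside, sorted by VIP. No
multiple-testing correction gates selection (the selection aims at ranking
dominant biological changes, not error-controlled discovery); a
Benjamini–Hochberg column is emitted for reference.

**Spearman correlation** pools all experimental observations of the arm
across the study period, optionally with the collection hour as a
pseudo-variable, and bands coefficients at ±0.2 and ±0.6 (high
positive / positive / neutral / negative / high negative). Constant variables
have undefined rho and are flagged rather than silently zeroed.

**Power.** The paired two-sided t-test power is analytic via the noncentral
t with df = n − 1 and noncentrality d√n: at d = 0.9, n = 12, α = 0.05 it is
0.810, the "acceptable power for a large effect" regime of a 12-subject
paired design. Monte-Carlo companions estimate the same quantity by
simulation and the Wilcoxon power under normal shifts (slightly lower, as its
asymptotic efficiency predicts).

## The synthetic generator

The generator exists so the whole pipeline can be exercised end-to-end
against a known truth. Concentrations follow a multiplicative lognormal
model:

value(s, m, t, arm) = baseline_m × exp(b_sm) × response_m(t, arm) × exp(ε),

with b_sm ~ N(0, subject_sd²) a per-(subject, metabolite) random effect
shared across arms and hours (each subject is their own control), ε ~ N(0,
noise_sd²) residual noise, and response ≡ 1 in the vehicle arm and for
unaffected metabolites. Response shapes interpolate log-linearly between
hourly anchors — early/late peak (rise to peak_fc at peak_time, then
geometric decay toward baseline at 0.45 per hour on the log scale),
persistent rise (plateau after the peak), monotone decrease (log-linear
decline to peak_fc < 1 at 4 h). Anchors rather than parametric kinetics,
because hourly means are all a study of this design observes.

`table1_preset()` plants 13 affected metabolites whose shapes, peak times,
peak fold changes and baselines follow the reference time-courses in
`table1_reference()` — an early-peaking lactic-like surge (FC ≈ 27 at 1 h), a
monotone vanillylmandelic-like decrease to ≈ 1/8.8 by 4 h, a persistent
tiglylglycine-like rise to ≈ 7, and so on — among 107 unaffected fillers in a
120-metabolite panel.

**Noise calibration.** The reference per-time coefficients of variation
(SD/mean) at baseline hours have median ≈ 0.6. A lognormal with total
log-scale SD 0.57 reproduces that (CV = √(exp(σ²) − 1) ≈ 0.61), split as
subject_sd = 0.35 between subjects and noise_sd = 0.45 residual — the split
itself is not identifiable from published per-time SDs, so it is a documented
modelling choice, not an estimate of the original cohort's variance
components. Creatinine is lognormal(log 10, 0.4) mmol/L per sample, so raw
and normalized views differ realistically.

With `include_qc_layout = TRUE`, each subject's batch is emitted in the exact
25-injection order of the measurement design — six leading QCs (five of which
condition the column), five vehicle and five alcohol samples in randomized
order interleaved with QCs, two alcohol repeats placed before the alcohol
block (repeats of samples injected later) and two vehicle repeats after the
vehicle block (repeats of samples injected earlier) — 11 QC + 5 + 5 + 2 + 2 =
25 injections. QCs carry the pooled mean profile plus small analytical noise
(log-SD 0.05); repeats duplicate their original plus the same noise.

**What the generator does not emulate** — and therefore what passing tests do
not show about real data: instrument drift within/between batches beyond QC
noise, period or carry-over effects of the crossover, correlated metabolite
modules (pathway structure), heavy-tailed or censored-at-LOQ noise beyond the
optional zero-inflation, and diurnal or dietary variation. Recovery results
on synthetic studies bound what the pipeline can do under its own model
assumptions; they are not a validation against biology.

## Numerical choices and degenerate inputs

- Rank checks: PCA and PLS-DA refuse k above the attainable rank and say
  what the bound is; SCA bounds k by levels − 1.
- Exactly collinear class profiles make PLS-DA degenerate (zero response
  covariance) — an error, not a silent zero-component model; VIP on a model
  with zero explained response variance is likewise an error.
- Zero-variance metabolites under auto scaling are excluded with a warning
  and recorded, keeping downstream fits well posed.
- Bi-plot ties break lexicographically by metabolite name; component signs
  follow the largest-|loading|-positive convention — both purely for
  determinism.
- All simulation entry points take explicit integer seeds; two runs with the
  same seed and configuration produce byte-identical output bundles.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration (12 subjects × 2 arms × 5
hours × 120 metabolites) for end-to-end checks, and smaller randomized
instances (up to 20 × 20 for the PCA/eigendecomposition equivalence, 100
random balanced designs for ASCA, 50 random paired vectors against the 2ⁿ
enumeration oracle, 50 seeded studies for recovery and null-calibration
rates). These sizes give stable pass/fail behaviour at fixed seeds while
keeping the default run desk-scale.

## Known limitations

- Main-effects-only ASCA; no interaction term or covariate-adjusted (GLM)
  variants for unbalanced designs.
- No cross-validation, permutation-based model statistics (Q², CV-ANOVA) or
  OPLS variants for the latent models.
- The unfolded construction is one defensible choice among several (an
  observation-rows unfolding with different centroid semantics is equally
  coherent); its documented identities are the contract, not equivalence to
  any particular published figure.
- Exact Wilcoxon p-values are conditional on observed ranks; with heavy
  tying the attained size can sit well below the nominal gate.
- The selection reports no error-rate guarantee: it is a ranked shortlist
  under three conventional gates, and the optional FDR column is advisory.
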