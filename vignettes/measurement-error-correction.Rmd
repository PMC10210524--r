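---
title: "Correcting diagnostic accuracy for biomarker measurement error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting diagnostic accuracy for biomarker measurement error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snroc)
```

## The problem

A continuous biomarker `X` discriminates cases (`Y = 1`) from controls
(`Y = 0`); its discrimination is summarized by the AUC
`pr(X₍₁₎ > X₍₀₎)` and by sensitivity `pr(X ≥ c | Y = 1)` and
specificity `pr(X < c | Y = 0)` at a cutoff `c` (larger marker values
indicate disease by convention; the package warns when the data are
oriented the other way). In practice `X` is observed only through noisy
assays,

```
W = X + U,                 M = α₀ + α₁ X + V,
```

with `U`, `V` and `X` mutually independent and the errors mean-zero.
Three designs map onto this model: replicates (`α₀ = 0, α₁ = 1`,
`σ_u = σ_v`), a clinical/research assay pair on a common scale
(`α₀ = 0, α₁ = 1`, `σ_u < σ_v`), and a research assay on a different
scale, linearly related to the marker (general `α₀, α₁`). Noise
attenuates every accuracy measure; the package quantifies and undoes
the attenuation.

## Binormal correction for attenuation

When both groups are normal with common variances, the noisy and true
AUC are linked exactly on the probit scale, giving the de-attenuation

```
A_x = Φ{Φ⁻¹(A_w) √(1 + λ²)},    λ² = σ_u²/σ_x²,
```

implemented in `correct_auc()`. Under unequal group variances the same
form holds with the Reiser ratio
`λ*² = (σ_u0² + σ_u1²)/(σ_x0² + σ_x1²)`. Sensitivity and specificity
use the group-specific ratios (`correct_sensitivity()`,
`correct_specificity()`); that correction is a large-sample
approximation, applied exactly as stated, with no finite-sample
adjustment. The corrections are exact algebraic inverses of the
attenuation map, which the test suite checks to machine precision.

Assumptions worth remembering: normality of marker *and* errors in each
group, independence of `X` and the errors, and a cutoff fixed in
advance. Under skewed markers the binormal correction is biased — the
motivation for the skew-normal estimator below.

## Identifying the error variances from two assays

Neither `σ_u²` nor `σ_x²` is observable from `W` alone. With a second
measure, the cross-moment does the work (`moments_two_unbiased()`):

```
mean(W·M) − mean((W+M)/2)²  →  σ_x²,
var(W) − σ_x²               →  σ_u²,      var(M) − σ_x²  →  σ_v².
```

All moments use the population (divisor-`n`) convention of the plug-in
estimators; the difference from divisor-`(n−1)` is `O(1/n)`. Negative
error-variance estimates — common in small samples when an assay is
nearly noiseless — are clamped to zero with a warning ("no detectable
assay noise"); a nonpositive `σ_x²` estimate is fatal, since the pair
then carries no common signal. For replicate designs,
`replicate_variance_components()` offers the classical within/between
decomposition of the same estimands.

A linearly biased `M` is calibrated through the outcome:
`α₁ = cov(Y, M)/cov(Y, W)`, `α₀ = mean(M − α₁W)`
(`linear_calibration()`), after which `M* = (M − α₀)/α₁` is unbiased
with error variance `σ_v²/α₁²`. This identification requires equal
error variances across disease groups, so under the calibrated model
the error variances are pooled (n-weighted) after per-group estimation;
under the unbiased-pair model they are kept per group, matching the
group-wise variance calculations that unequal-variance corrections
need. This per-group versus pooled split was a genuinely open design
point; the package resolves it by following what each identification
strategy can actually support.

The variance-optimal composite uses inverse-variance weighting:
`γ = σ_v²/(σ_u² + σ_v²)`, composite error variance
`σ_u²σ_v²/(σ_u² + σ_v²) ≤ min(σ_u², σ_v²)`. When both estimated error
variances are zero any weight is equivalent; γ = 0.5 by convention.

## The skew-normal correction estimator

The skew-normal family `SN(ξ, ω, α)` with density
`(2/ω)φ(z)Φ(αz)`, `z = (x−ξ)/ω`, spans symmetric (`α = 0` is normal)
and skewed shapes with third standardized moment bounded by
±0.99527. Its first three moments are rational in
`δ = α/√(1+α²)`:

```
E(X)   = ξ + ωδ√(2/π)
var(X) = ω²(1 − 2δ²/π)
skew   = {(4−π)/2} (δ√(2/π))³ / (1 − 2δ²/π)^{3/2}.
```

Because symmetric, independent error leaves the mean and the third
central moment of `W` equal to those of `X` and inflates the variance
by exactly `σ_u²`, matching the SN moments to `(W̄, S²_W − σ_u², m₃/(S²_W
− σ_u²)^{3/2})` fits the *true* marker distribution from noisy data
(`fit_group_sn()`). Corrected sensitivity/specificity are the fitted
CDF tails, the ROC curve is traced over a cutoff grid, and the AUC is
its trapezoidal integral (`sn_roc()`, `sn_auc()`). The full two-assay
pipeline (`sn_wm_estimate()`) fits the optimal composite series with
its composite error variance by default; a flag restricts it to `W`
alone.

### Numerical choices

- **Skewness equation.** The moment map is solved in `δ`, where it is
  strictly monotone on `(−1, 1)`, by bracketed root-finding to 1e-14:
  the root is unique, sidestepping the multiple-root ambiguity of
  solving in `α` directly (distinct `α` roots correspond to the same
  distribution; the `δ` parameterization collapses them).
- **Infeasible skewness.** Sample skewness at or beyond the SN bound
  (0.99527, within 1e-6) cannot be matched; the fit clamps
  `δ = ±(1 − 1e-6)` (|α| ≈ 700), warns (condition class
  `snroc_feasibility`), and sets a `clamped` flag rather than failing —
  essential inside bootstrap resamples, and relevant in practice
  because strongly log-normal-like data sit near the boundary.
- **CDF.** `psn()` uses the Owen's-T identity `F(z) = Φ(z) − 2T(z, α)`
  with `T` computed by 96-node Gauss–Legendre quadrature after reducing
  to `|a| ≤ 1` via the standard reflection identity; agreement with
  adaptive quadrature of the density is at the 1e-12 level across
  shapes up to |α| = 10.
- **ROC grid.** 2001 cutoffs spanning the `1e-6 … 1−1e-6` quantile hull
  of both fitted distributions; doubling the grid moves the AUC by less
  than 1e-4 (asserted in tests). The trapezoidal AUC agrees with direct
  quadrature of `∫ f₀(x){1 − F₁(x)}dx` within 2e-4.
- **Sampling.** `rsn()` uses the exact representation
  `Z = δ|N₁| + √(1−δ²)N₂`, not inverse-CDF, for speed.

## Cutoff rules

Population-level rules operate on true or fitted distributions over a
4001-point quantile-hull grid; data-driven rules search the sorted
unique observed values of the unbiased assay. Implemented rules:
minimum distance to the perfect-test corner (argmin of
`(1−Se)² + (1−Sp)²`), the Youden index, and best specificity subject to
a sensitivity floor (default 75%). Ties break to the smallest cutoff.
In the simulation harness the cutoff is computed once per scenario from
the *true* distributions and held fixed across replicates — the
corrections assume a pre-determined cutoff, and re-estimating it per
replicate would mix cutoff variability into the comparison.

## Bootstrap inference

`bootstrap_accuracy()` resamples cases and controls separately with
replacement (every resample keeps `n₀` and `n₁`) and reruns the entire
pipeline — identification, calibration, combination, fitting — per
resample. Defaults: B = 200 resamples and normal-theory intervals
(estimate ± 1.96·SE, truncated to [0, 1]), the conventional companion
to average-standard-error reporting; percentile intervals are available
by flag and the harness records which was used. Within resamples,
empirical probabilities are clipped to `[1e-10, 1−1e-10]` before the
probit (a resample can put all cases above the cutoff); direct calls
reject boundary values instead, keeping estimator semantics strict.
Per-resample seeds derive deterministically from one master seed.

## The simulation harness

`generate_data()` emulates a case-control biomarker study: controls
drawn from the chosen family standardized to mean 3 and SD 1 (assay
data are positive in practice, and results are location-invariant),
cases from the same family with the mean shifted by `ln 3.2`
(AUC ≈ 0.79–0.88 depending on family), additive normal assay errors,
and exactly `⌈n/2⌉` cases — deterministic allocation, reducing
Monte-Carlo variance relative to binomial sampling. Defaults: n = 300,
disease rate 50%, 500 replicates. Families:

- `normal`: `N(3, 1)`; true AUC `Φ(ln 3.2/√2) = 0.7946`, and the
  min-distance cutoff is the midpoint `3 + ln(3.2)/2`, where
  Se = Sp = `Φ(ln 3.2/2) = 0.7196`.
- `skew_normal`: `SN(0, 1, α = 6)` standardized; shape 6 by default,
  overridable via `sn_shape`. True AUC by quadrature ≈ 0.806
  (the truth is computed under whichever shape is configured, so the
  harness stays internally consistent under any override).
- `log_normal`: `exp(N(1, 0.3²))` vs `exp(N(1.5, 0.3²))`; true AUC
  `Φ(0.5/(0.3√2)) = 0.8807` by the log-scale closed form. Control
  skewness ≈ 0.95 — deliberately just inside the skew-normal
  feasibility bound.

Error presets `T1`–`T5` cover σ_u = σ_v ∈ {0.71, 1, 1.22}, the
clinical/research pair (0.2, 1), and the calibrated design
(`M = 0.2 + 0.8X + V`). `run_table()` compares five estimators —
naive-M, CFA-W, CFA-M, CFA-WM, SN-WM — reporting bias, SD across
replicates, and (when bootstrapping is enabled) average bootstrap SE
and 95% coverage. Replicate-level failures are dropped and counted.
Typical problem sizes: the shipped checks use 500 replicates of n = 300
without bootstrap (a few seconds) and enable the B = 200 bootstrap only
for targeted coverage runs, which are the slow path.

```{r harness, eval = FALSE}
res <- run_table(scenario_preset("T3", family = "skew_normal"),
                 reps = 500)
subset(res, measure == "auc")
```

What the generator does *not* emulate: heteroscedastic or multiplicative
assay error, error distributions that are themselves skewed,
zero-inflated markers, verification bias, or covariate structure.
Passing simulations therefore demonstrate correctness of the estimators
under additive, normal, homoscedastic-within-group error — the model
the corrections are derived for — not robustness beyond it. The SN
correction estimator is likewise not consistent for arbitrary marker
distributions (the log-normal family shows small residual bias); it is
a flexible parametric compromise where nonparametric deconvolution
would be impractical.

## Known limitations

- The Se/Sp de-attenuation is a large-sample approximation; small-n
  bias is visible in its finite-sample behaviour.
- Calibration of a biased assay (`linear_m`) requires equal error
  variances across groups and a marker genuinely associated with the
  outcome (`cov(Y, W)` bounded away from 0).
- Markers with |skewness| at the SN bound fit at the clamped boundary;
  interpret `clamped = TRUE` fits cautiously.
- No validation-subset or replicate-free (single-assay) identification:
  two measures per subject are required for all corrected estimators.
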