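---
title: "Methods behind hytrait: simulation, active learning, GPR and spectral reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind hytrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hytrait)
```

## The retrieval problem

Imaging spectrometers in the 400–2500 nm range deliver hundreds of
contiguous, strongly collinear reflectance bands per pixel. Hybrid
retrieval turns these spectra into crop traits — specific leaf area (SLA,
cm²/g), leaf area index (LAI, m²/m²), canopy chlorophyll and water
content (CCC, CWC, g/m²), FAPAR and fractional vegetation cover (FVC) —
by training a statistical regressor on simulated pairs of (spectrum,
trait) and applying it to measured pixels. Two practical obstacles shape
the design: the training pool must be reduced to a compact, informative
subset (sampling-domain reduction), and the spectral dimension must be
compressed before a kernel regressor becomes both slow and unstable on
redundant bands (spectral-domain reduction). `hytrait` implements the
full chain and both competing spectral strategies — 20 principal
components (PCA) versus the 20 most relevant bands from sequential
backward band removal (BR) — with per-pixel predictive uncertainty.

## The surrogate canopy simulator

Full radiative-transfer models are deliberately out of scope. The
training library is produced by a declared surrogate whose purpose is to
give the pipeline the statistical structure the method assumes —
trait-driven, nonlinear, strongly collinear spectra with realistic
soil/vegetation mixing — not radiometric fidelity. All constants below
are package defaults, overridable through `simulator_config()`.

**Leaf level.** Constituent absorption spectra are sums of unit-Gaussian
features: chlorophyll at 430/660 nm, carotenoids at 470 nm, water at
970/1200/1450/1940 nm, dry matter at 1730/2100/2300 nm — centers chosen
to sit on the well-known pigment, water and dry-matter features. With
contents `Cab` (µg/cm²), `Cxc` (µg/cm²), `Cw` (g/cm²), `Cm` (g/cm²) and
structure parameter `N`, the Beer–Lambert-style absorption coefficient is

    a(λ) = (Cab·k_ab + Cxc·k_xc + Cw·k_w + Cm·k_m) / N,

absorptance `A = 1 − exp(−a)`, and leaf reflectance
`ρ_leaf = ρ₀ + s_N (1 − A)` with `ρ₀ = 0.02`,
`s_N = 0.46 + 0.05 (N − 1.5)`. The scattering constants were picked once
to put the NIR plateau near 0.45–0.50, typical of green leaves.

**Canopy level.** The nadir gap fraction follows the Beer–Lambert law
`P = exp(−k_ext · LAI)` with `k_ext = 0.5 (1 + 0.3 · LIDF)` — 0.5 for a
spherical leaf-angle distribution (`LIDF = 0`), the standard nadir
value; the literature the workflow builds on leaves the extinction
coefficient unspecified, so this declared form is a package choice, not
an inferred one. Canopy reflectance mixes leaf and soil by gap fraction,
with a multiple-scattering gain `q = 0.8` on the vegetated part and a
weak declared geometric modulation `g_geo` in the sun/view angles
standing in for BRDF effects:

    R(λ) = g_geo · [ (1−P) ρ_leaf (1 + q (1−A)) + P · R_soil ], clipped to [0,1].

**Soil.** `R_soil = α_soil · B_soil · r₀(λ) · (1 − 0.7 (SMC/100) w̄(λ))`,
a brightness-scaled linear baseline (0.10 → 0.35 over 400 → 2400 nm)
darkened by moisture through the max-normalized water shape. The soil
position variables (`BSM_lat`, `BSM_lon`) are sampled to honor the
declared input table but are spectrally inert — a documented limitation.

**Targets.** `FVC = 1 − P`; `FAPAR = (1 − P) · mean A(λ)` over
400–700 nm (an interception × absorptance surrogate — an energy-balance
FAPAR would require the full flux model); `CCC = LAI · Cab · 10⁻²`;
`CWC = LAI · Cw · 10⁴`; `SLA = 1/Cm`. Since mean PAR absorptance ≤ 1,
`FAPAR ≤ FVC` always holds.

**Input distributions.** `default_trait_specs()` encodes the standard
parameterization: truncated Gaussians for the leaf constituents and soil
descriptors (e.g. `Cab` ~ N(45, 35²) truncated to [0, 80] µg/cm²),
uniforms for carotenoids, LAI ∈ [0.1, 8], leaf inclination ∈ [−1, 1] and
the sun/view geometry. Truncation is realized by rejection sampling, not
clipping, so the truncated densities carry no boundary atoms.
Anthocyanins and senescent material are fixed at zero: the scheme models
green canopies only.

**What the generator does and does not emulate.** It reproduces
trait-driven absorption features, gap-fraction mixing, inter-band
collinearity (a 2000-sample library on a ~200-band grid concentrates
>99.99% of variance in its first 20 principal components) and
non-vegetated surfaces (bright/dark soil, water, man-made archetypes
with multiplicative jitter, all trait targets zero). It does not emulate
sensor noise, atmospheric residuals, senescent vegetation, directional
hot-spot effects or real soil spectral diversity. Tests passing on this
generator therefore validate the *pipeline machinery* — selection rules,
estimators, bookkeeping, uncertainty propagation — not retrieval
accuracy on real scenes.

## Band grids, resampling and exclusion windows

Spectra are simulated on a fine 1 nm grid and resampled through Gaussian
spectral response functions: band value = Σ w·R / Σ w with
`w = exp(−4 ln2 (λ−c)²/FWHM²)`, truncated at ±2 FWHM and renormalized —
exact for constant spectra and linear in the input. Two presets ship:
uniform 10 nm over 400–2500 nm (211 bands) and uniform 7 nm over
400–2346 nm; the true band layout of upcoming operational spectrometers
is unpublished, and neither preset claims to be it. Thirteen
atmospheric-absorption windows (`default_exclusion_windows()`; union
semantics, membership by band center) remove ~84 of the 211 bands. The
kept-band index is recorded in metadata and mapping aligns cube bands to
the model *only* through that recorded metadata — never by
nearest-wavelength guessing; mismatches are hard errors.

## Gaussian process regression with ARD

The regressor is a zero-mean (after target centering) GP with the
automatic-relevance-determination rational quadratic kernel

    K(x_i, x_j) = σ_f² (1 + D_ij / 2α)^(−α),   D_ij = Σ_m (x_im − x_jm)²/σ_m²,

which behaves as a scale mixture of squared exponentials (and converges
to one as α → ∞). Predictions use the analytic posterior mean
`k*ᵀ(K+σ_n²I)⁻¹y` and latent variance `k** − k*ᵀ(K+σ_n²I)⁻¹k*`; the
per-pixel coefficient of variation is `100·SD/|mean|`. Hyperparameters
maximize the log marginal likelihood with L-BFGS-B in log-parameter
space, with analytic gradients (verified against central finite
differences at 1e-5 relative accuracy) and multi-start restarts.

Numerical choices: features are z-scored and targets centered with
training statistics (stored in the model, so predictions return original
units); initialization σ_f² = var(y), α = 1, σ_n² = 0.01·var(y), and
lengthscales √B per (standardized) feature so the typical scaled squared
distance is O(1) regardless of feature count; a jitter ladder
(0 → 1e-6·σ_f²) rescues failed Cholesky factorizations; numerically
negative predictive variances are clipped at zero with a warning;
reaching the iteration cap is treated as a budget choice, not a failure.

Band relevance converts fitted lengthscales into a 0–100 score
(smaller lengthscale = more relevant). The conversion is max-normalized,
`r_m = 100 (1 − σ_m²/max σ_m²)`; a sum-normalized variant is available
(`method = "sum"`). Both are monotone decreasing in σ_m², which is the
only property downstream code relies on.

## Active learning in the sampling domain

The pool-based Euclidean-distance-based diversity (EBD) loop starts from
a random seed set (default 200 = 10% of the 2000-sample pool),
repeatedly proposes the candidate maximizing the minimum squared
Euclidean distance to the current training set, and accepts it only if
the RMSE on a reference set strictly decreases; rejected candidates are
discarded permanently (prevents livelock; whether re-proposal should be
allowed is genuinely open, and permanent discard is the package's
choice). The loop stops at 500 accepted samples by default, or earlier
on pool exhaustion — early convergence is reported, not an error.
Spectra are compressed to 20 pool-fitted principal components *inside*
the loop only (the reference is projected with the same transform); the
returned library preserves all bands.

Hyperparameters are re-optimized every `refit_every = 50` acceptances
(warm-started) rather than at every proposal; a refit is kept only when
it does not worsen the reference RMSE, so the recorded learning curve is
non-increasing by construction. Between refits each candidate is
evaluated by an exact weight-vector refit under the current kernel. The
curve is logged per acceptance. For targets without reference data
(FAPAR, FVC) a bypass draws N random pool samples (default 1000).
After optimization, 26 zero-labelled non-vegetated spectra are appended
so models learn to map soil, water and man-made surfaces near zero; the
archetype proportions (35/25/20/20% bright soil/dark soil/water/
man-made) are a package default, since no canonical composition exists.

## Spectral reduction: PCA versus band ranking

**PCA.** Loadings come from the SVD of the centered reflectance matrix
(equivalently the eigenvectors of the band covariance; reflectance
shares units across bands, so no per-band standardization), with a
deterministic sign convention (largest-magnitude loading element
positive). The component count rule keeps the smallest number exceeding
99.95% cumulative variance, with a fixed-20 floor in the standard
configuration — on simulated libraries the threshold is met long before
20, so the fixed mode governs.

**SBBR.** Sequential backward band removal wraps the GP: under a fixed
seeded 3-fold partition (fixed folds keep iterations comparable), a GP
is fitted per fold on the surviving bands; per-fold lengthscales are
ranked and the band with the largest mean rank (consensus "least
relevant"; the aggregation rule across folds is a package choice) is
removed; iterate to a single band. The per-iteration table records the
surviving count, wavelengths and the cross-validated R² mean/SD/min/max;
the final ranking is the removal order reversed, and the 20-band setting
is the surviving set at the 20-band iteration. Fold fits warm-start from
the previous iteration with the removed lengthscale dropped
(`from_scratch = TRUE` refits from the default initialization; whether
the reference procedure refits from scratch each iteration is unstated,
so both are provided).

## End-to-end strategies and mapping

`run_strategy()` composes: pool (simulated or supplied) → exclusion
windows → AL (or random bypass) → zero-labelled augmentation → {20 PCs |
20 ranked bands | all bands} → GP fit → evaluation. `map_traits()`
applies a bundle per pixel and returns estimate, SD and CV% grids.
Estimates are *not* clipped to physical ranges by default — out-of-range
values are a useful diagnostic of model extrapolation — though an
optional clamp exists. In BR mode the wrapper ranks bands on a seeded
subsample of the training rows (default 200): the backward elimination
refits O(B²) GPs and full-library wrapping is a server-scale job, while
the subsampled ranking recovers the same relevant bands on simulated
data; the final 20-band model is always fitted on all rows.

## Evaluation statistics

`goodness_of_fit()` reports RMSE (target units), RRMSE = 100·RMSE/mean
of observations (the conventional reading of "relative RMSE"), NRMSE =
100·RMSE/range of observations, and R². R² defaults to the squared
Pearson correlation between observed and predicted; reported validation
tables in this literature combine large relative errors with moderate
R², which is consistent with the correlation form and not with the
coefficient of determination about the 1:1 line, so the correlation form
is the default and the 1:1 variant sits behind `r2 = "cod"`.
`model_consistency()` compares two co-registered maps (R², bias, RMSE,
scatter table); `relevance_export()` lays the 20 feature relevances on a
polar layout (angle 2πk/20, radius = relevance).

## Problem sizes used by the test and demonstration runs

Module tests run on coarse grids (30–150 nm spacing) and small libraries
(tens to hundreds of samples). The full-scale properties use: a
2000-sample library on the 10 nm grid (127 bands after exclusion) for
the PCA variance rule; pool 2000 / reference 100 / budget 300 over five
paired seeds for the AL-versus-random comparison; ten seeded 40-band
planted-signal runs for SBBR recovery; and a 50×50-pixel scene with a
1000-sample pool and 500-sample bypass (the standard 1:2 bypass-to-pool
ratio at half size) on a 30 nm grid for the dual-strategy mapping
demonstration. These sizes are the package's declared desk scale; the
statistical conclusions they support are qualitative (AL ≥ random,
planted bands recovered, both strategies consistent), not accuracy
claims about any real sensor.

## Known limitations

- The surrogate's radiometry is schematic; absolute accuracies obtained
  on it do not transfer to real scenes.
- FAPAR is an interception×absorptance proxy, not an energy-balance
  quantity.
- Soil position variables are spectrally inert.
- Featureless flat-gray (man-made) spectra can defeat the band-ranking
  strategy for weakly expressed traits such as SLA: ARD prunes bands
  that carry no within-library signal, and on the surviving bands a flat
  spectrum may sit close to the vegetated manifold, pulling its estimate
  toward vegetated values instead of zero. The PCA strategy, which keeps
  a global low-dimensional summary, maps the same pixels near zero. The
  hyperparameter box (mixture exponent bounded away from its heavy-tail
  corner) prevents the related degenerate evidence maximum.
- The AL accept rule optimizes against the same reference used for its
  learning curve; an independent test set is the user's responsibility.
- Heteroscedastic noise, sparse GP approximations and uncertainty-based
  AL variants are out of scope.
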