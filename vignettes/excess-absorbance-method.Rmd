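---
title: "The excess-absorbance method for dye self-aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The excess-absorbance method for dye self-aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excessabs)
```

## The model and its assumptions

A dye D in solution is assumed to take part in a single association
equilibrium
$$ nD \rightleftharpoons D_n, \qquad K_n = \frac{C_n}{C_1^n}, $$
with $C_1$ the monomer and $C_n$ the aggregate concentration and $n \ge 2$
an integer. Three simplifications define the model's scope:

1. infinite-dilution optical properties reflect only dye–solvent
   interactions (the reference state is the infinitely dilute solution);
2. a single equilibrium holds over the whole concentration range —
   coexisting dimer/trimer/... equilibria are out of scope;
3. the integral extinction coefficients $\bar\epsilon_1, \bar\epsilon_n$
   are concentration-independent.

The observable is the *integral absorbance* $\bar A(C)$, the trapezoidal
area of absorbance over a band window $[\lambda_1, \lambda_2]$, which for
two absorbing species reads
$\bar A = \bar\epsilon_1 \ell C_1 + n \bar\epsilon_n \ell C_n$ with the
material balance $C = C_1 + n C_n$. The *excess absorbance*
$$ \Omega(C) = \bar A(C) - \bar\epsilon_1 \ell C $$
measures the deviation from the Lambert–Beer ideal anchored at the
infinite-dilution slope $\bar\epsilon_1 \ell$. Eliminating $C_1, C_n$
gives the key working equation
$$ C = a\,\Omega + b\,\Omega^{1/n}, \qquad a = \frac{1}{\Delta_n},\quad
   b = (n K_n \Delta_n)^{-1/n}, \quad
   \Delta_n = |\bar\epsilon_1 - \bar\epsilon_n|\,\ell > 0 . $$

### Sign convention

$\Omega$ is negative when $\bar A(C)$ is concave
($\bar\epsilon_1 > \bar\epsilon_n$) and positive when convex. For
numerical stability the fit always uses a rectified $\Omega > 0$ together
with $\Delta_n > 0$; the curvature, classified from the sign of the summed
raw excess, then decides the *sign* used when recovering
$\bar\epsilon_n = \bar\epsilon_1 \mp \Delta_n/\ell$ (minus for concave).
We deliberately use this absolute-value convention throughout rather than
attaching a sign to $\Delta_n$ per curvature case, which is ambiguous.

## The fitting procedure

For each candidate integer $n$ in the scan range (default 2–10) the pair
$(a, b)$ is fitted by **non-negative least squares** — both coefficients
are intrinsically positive — and the candidate with minimal RMSE is
selected. Residuals are measured in concentration units: the key equation
expresses $C$ as a function of $\Omega$, so $C$ is the fitted response.
Ties break toward smaller $n$ (parsimony), and a runner-up RMSE within 5%
of the minimum triggers a warning, since near-ties between adjacent $n$
are common on narrow concentration ranges. Inverting the coefficients at
the selected $n$ yields
$$ \Delta_n = 1/a, \qquad K_n = \frac{a}{n\,b^{\,n}} . $$
This inversion is the unique reading consistent with the key equation and
is enforced by a round-trip identity test (regenerating the curve from the
extracted parameters and refitting reproduces $(a, b)$ to $10^{-9}$).

The **reliability check** closes the loop: with the extracted
$(n, K_n)$ the monomer-fraction polynomial
$$ (n K_n C^{n-1})\,\xi^n + \xi - 1 = 0, \qquad \xi = C_1/C, $$
is solved at every measured concentration, the speciation is formed, and
$\bar A_{calc}$ is compared with $\bar A_{exp}$ through a through-origin
regression slope (1 for a perfect model) and the maximum relative
deviation. Through-origin regression is used both here and for the
limiting slope because the physics forces both lines through the origin;
whether a free intercept was ever intended elsewhere is not specified, so
the package fixes the origin-constrained choice and documents it.

### Estimating the reference slope, and why it is refined

Two direct estimators of $\bar\epsilon_1 \ell$ are provided:
`linear3` (through-origin line on the three lowest points) and `smooth5`
(Savitzky–Golay smoothing, degree 2, 5-point frame — chosen over a plain
moving average because it preserves quadratic trends exactly — followed by
a through-origin parabola on the five lowest points, whose derivative at
$C = 0$ is the slope).

Both are unbiased only if the lowest measured concentrations are
effectively pure monomer. On grids like 6–44 µM (methylene blue) or
20–133 µM (fluorescein in acetonitrile) they are not: the lowest points
already hold ~1% aggregate, the slope inherits a deterministic bias of the
same order as $\Omega$ itself at the dilute end, and — as direct numerical
experiments during development showed — the RMSE scan then selects a wrong
$n$ *even for noiseless data*. Because the data at the true slope satisfy
the key equation exactly, the slope is best treated as a nuisance
parameter. With `refine_slope = TRUE` (default), for each candidate $n$
the pipeline minimizes the reliability-reconstruction residual
$\sum_i (\bar A_{calc,i}(s) - \bar A_{exp,i})^2$ over the reference slope
$s$ within $\pm 40\%$ of the direct estimate, and the scan compares
candidates at their own refined slopes, still selecting by the
key-equation RMSE. The reconstruction residual is anchored to the full
nonlinear speciation model, so a wrong $n$ cannot absorb the slope freedom
(profiling the key-equation RMSE itself, by contrast, lets small $n$
overfit and was rejected). For the true $n$ and noiseless data the
residual reaches zero at the true slope, restoring exact identifiability.

The 1-D profile is minimized by successive grid zooming (21-point grids,
bracket shrunk to the best point's neighbourhood until narrower than
$10^{-8}$ of the initial slope) rather than golden-section search: the
residual has kinks where the NNLS active set changes or a point's
rectified excess changes sign, and a needle-sharp minimum in the noiseless
limit, both of which defeat smooth 1-D optimizers.

## Numerical choices

* **Speciation root.** $f(\xi) = \alpha \xi^n + \xi - 1$ with
  $\alpha = n K_n C^{n-1}$ has $f(0^+) < 0 < f(1)$ and $f' > 0$: the root
  is unique in $(0, 1]$. It is found by Brent's method on
  $[10^{-16}, 1]$ (tolerance $10^{-14}$) and polished with three Newton
  steps, which brings the residual to machine precision. For
  $\alpha > 10^{12}$ the substituted variable $u = \alpha \xi^n \in (0,1)$
  avoids overflow.
* **Species concentrations.** $C_n$ is evaluated as $K_n C_1^n$ in log
  space instead of $(C - C_1)/n$, which cancels catastrophically when
  $\xi \to 1$; with the polished root both the material balance and the
  equilibrium law then hold to near machine precision.
* **NNLS.** With only two regressors the optimum is found exactly by
  enumerating the $2^2$ active sets; a dense grid search over
  $(a, b) \ge 0$ serves as the independent oracle in the tests.
* **Quadrature.** Trapezoidal rule on the recorded wavelength grid, with
  window endpoints linearly interpolated; exact for piecewise-linear
  spectra, and refining the grid by linear interpolation leaves the value
  unchanged.
* **Degenerate inputs.** Pure Lambert–Beer data (all $\Omega = 0$) abort
  with "no usable excess signal"; rectified points $\le 0$ are dropped,
  not clamped, because clamping would bias the $\Omega^{1/n}$ regressor;
  a fit with an inactive coefficient ($a = 0$ or $b = 0$) cannot be
  inverted and is reported as degenerate.
* **Uncertainty.** A case-resampling bootstrap over the $(\Omega, C)$
  pairs at the selected $n$ (percentile interval, default 200 replicates,
  deterministic under a seed) replaces instrument repeats, which an
  analysis package cannot perform; replicates with degenerate fits are
  discarded and more than 20% discarded is an error.

## The synthetic-data generator

`dye_preset()` encodes three systems used for validation, with Gaussian
bands whose areas realize the model's integral extinction coefficients:

| preset | n | $K_n$ | $\bar\epsilon_1$ | $\bar\epsilon_n$ | grid (µM) | window (nm) |
|--------|---|-------|------------------|------------------|-----------|-------------|
| `fs_upw` (fluorescein/water) | 3 | $1.4\times10^{9}$ M⁻² | 0.241 | 0.027 | 0.518–133 | 390–552 |
| `fs_acn` (fluorescein/acetonitrile) | 3 | $6.3\times10^{6}$ M⁻² | 0.04 | 0.389 | 20–133 | 390–552 |
| `mb_upw` (methylene blue/water) | 4 | $1.15\times10^{13}$ M⁻³ | 1.0 | 0.25 | 6–44 | 500–800 |

The `fs_acn` monomer coefficient (only known to be "small") and the
`mb_upw` extinction pair are explicit stand-ins, not measured values;
recovery of $K_n$ is insensitive to them. Band centers follow the real
systems (486 nm for fluorescein; 661/615 nm monomer/aggregate for
methylene blue); band widths are stand-ins chosen so each window captures
more than four sigma of every band, keeping band-truncation error below
0.1%. Concentration grids are 24-point geometric series over each system's
range — the shape of a serial dilution, dense where the limiting slope is
estimated.

Noise is multiplicative Gaussian (photometric noise scales with signal),
default 1%. `generate_spectra()` applies it independently per wavelength
point on a 1-nm grid, so band integration averages it down to roughly
0.1% on $\bar A$; `generate_curve()` skips the spectral realization and
applies the 1% directly to $\bar A$, a deliberately harsher corruption
useful for stress-testing. An optional relative error on the prepared
concentrations (`conc_noise_rel`) is available and off by default.

What the generator does **not** emulate: vibronic structure and secondary
peaks, solvent-dependent band shifts, baseline drift and scattering, and
wavelength-correlated instrument noise. Passing the round-trip tests
therefore shows the *estimator* is correct and noise-stable under the
model's own assumptions — it does not certify the two-species,
single-equilibrium model for any particular real dye.

## Problem sizes used in the tests

The round-trip suites use 20 noisy replicates per preset (24 concentration
points each), 100 replicates for the bootstrap-coverage and
slope-robustness simulations, and 6–10 randomly drawn models (n from 2 to
6, 30-point grids spanning the dilute to strongly aggregated regime) for
the exact-recovery property. These sizes give stable medians and counts
while keeping the whole suite at a few minutes on one core.

## Known limitations

* Simultaneous equilibria (mixtures of aggregate sizes) are explicitly out
  of scope; if two equilibria overlap in the concentration window, the
  single-n fit brackets rather than resolves them.
* Model selection rests on the raw RMSE minimum. Adjacent n are often
  nearly tied (the runner-up warning reports this); no information
  criterion is layered on top.
* With strong noise applied directly to the integral absorbance (1% on
  $\bar A$, as `generate_curve()` does), the n = 4 vs 5 distinction on the
  narrow methylene-blue grid is genuinely unidentifiable in a sizable
  fraction of replicates; the spectral noise route, which matches how
  photometric noise actually enters, does not have this problem.
* The extracted $\bar\epsilon_n$ inherits the reference slope's error
  amplified by $\Delta_n$; its uncertainty is typically several times that
  of $\bar\epsilon_1$.
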