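# excessabs

Quantifying dye self-aggregation in solution from UV-Vis absorption
spectra via **excess absorbance**.

Many dyes of biomedical interest (sodium fluorescein, methylene blue, ...)
self-associate in solution: `n` monomers D form an n-mer Dₙ through a single
equilibrium

```
n D  ⇌  Dₙ          Kₙ = Cₙ / C₁ⁿ     [Kₙ] = M^(1−n)
```

Because the monomer and the aggregate have different absorption
coefficients, the measured absorbance stops being proportional to the total
concentration — the solution deviates from the Lambert–Beer "ideal". This
package turns that deviation into the thermodynamics of the equilibrium:
the aggregation number `n`, the equilibrium constant `Kₙ`, and the
aggregate's integral extinction coefficient `ε̄ₙ`.

## Method

Each spectrum of a concentration series is reduced to its **integral
absorbance** Ā(C), the trapezoidal area of absorbance over a band window
[λ₁, λ₂]. With ε̄₁ℓ the limiting slope of Ā(C) at infinite dilution (ℓ the
path length), the **excess absorbance**

```
Ω(C) = Ā(C) − ε̄₁ ℓ C
```

is negative for a concave Ā(C) (ε̄₁ > ε̄ₙ) and positive for a convex one;
it is rectified to Ω > 0. Substituting the two-species absorbance and the
material balance C = C₁ + nCₙ into the equilibrium law gives the key
equation

```
C = a Ω + b Ω^(1/n),    a = 1/Δₙ,   b = (n Kₙ Δₙ)^(−1/n),
Δₙ = |ε̄₁ − ε̄ₙ| ℓ
```

which is linear in the transformed data. For every integer n = 2, 3, ... the
pair (a, b) is fitted by non-negative least squares; the n minimizing the
RMSE is the aggregation number, and inverting the coefficients yields
`Kₙ = a/(n bⁿ)` and `ε̄ₙ`. A reliability check then re-solves the
speciation polynomial `(n Kₙ C^(n−1)) ξⁿ + ξ − 1 = 0` at every measured
concentration and compares the reconstructed absorbance with the measured
one. Uncertainty on Kₙ comes from a case-resampling bootstrap.

When the most dilute measured samples still contain aggregate, the directly
estimated limiting slope is biased and can distort the selected n. The
pipeline therefore (by default) refines the reference slope per candidate
n by minimizing the reliability-reconstruction residual — see the methods
vignette (`vignettes/excess-absorbance-method.Rmd`) for details.

## Worked example

Synthetic fluorescein-in-water data (trimer, generating K₃ = 1.4×10⁹ M⁻²,
ε̄₁ = 0.241, ε̄₃ = 0.027) with 1% noise:

```r
library(excessabs)
sc    <- dye_preset("fs_upw", noise_rel = 0.01, seed = 7)
curve <- generate_curve(sc)
fit   <- fit_aggregation(curve, n_boot = 200, seed = 11)
print(fit)
#> Aggregation equilibrium fit (excess absorbance)
#>   selected n      : 3
#>   K_n             : 1.292e+09 M^-2
#>   eps1 (monomer)  : 0.2408 AU nm/(M cm)
#>   epsn (aggregate): 0.02521 AU nm/(M cm)
#>   delta_n         : 0.2156 AU nm/M
#>   curvature       : concave
#>   slope method    : linear3+refined
#>   reliability     : A_calc = 0.9998 A_exp (max rel dev 0.0229)
#>   K bootstrap CI  : [1.202e+09, 1.449e+09]
```

The fit recovers the trimer, the equilibrium constant within 8% and both
extinction coefficients within a few percent of the generating values; the
reliability slope of 0.9998 says the fitted model reproduces the measured
integral absorbances essentially exactly. Real measurements come in as
plain-text spectra via `read_spectra_series()` followed by
`fit_aggregation(series, window = band_window(390, 552))`.

A command-line wrapper covers the same workflow:

```sh
Rscript inst/cli/excessabs.R simulate --preset fs_upw --seed 7 --out fs.csv
Rscript inst/cli/excessabs.R fit fs.csv --window 390:552 --out report.json
Rscript inst/cli/excessabs.R report report.json
```

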