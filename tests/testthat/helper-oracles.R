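# Independent oracles and fixture builders shared across the suite.

# 1000-step bisection for the monomer-fraction polynomial on (0, 1):
# independent of the package's Brent/Newton solver.
bisect_xi <- function(n, K, C, steps = 1000) {
  alpha <- n * K * C^(n - 1)
  f <- function(xi) alpha * xi^n + xi - 1
  lo <- 0; hi <- 1
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Dense grid search oracle for the two-column non-negative least squares.
grid_nnls <- function(X, y, a_hi, b_hi, k = 200) {
  a_grid <- seq(0, a_hi, length.out = k + 1)
  b_grid <- seq(0, b_hi, length.out = k + 1)
  best <- c(a = 0, b = 0, rss = sum(y^2))
  for (a in a_grid) {
    r1 <- y - a * X[, 1]
    rss_b <- vapply(b_grid, function(b) sum((r1 - b * X[, 2])^2), numeric(1))
    j <- which.min(rss_b)
    if (rss_b[j] < best[["rss"]])
      best <- c(a = a, b = b_grid[j], rss = rss_b[j])
  }
  best
}

# Noiseless absorbance curve straight from the forward model.
model_curve <- function(model, C) {
  absorbance_curve(C, predict_integral_absorbance(model, C),
                   path_length = model$path_length)
}

# Random aggregation model with appreciable aggregation at the top of a wide
# geometric grid (so the dilute limit is genuinely reached at the bottom).
random_model_case <- function() {
  n <- sample(2:6, 1)
  eps1 <- runif(1, 0.1, 2)
  epsn <- eps1 * if (runif(1) < 0.5) runif(1, 0.05, 0.6) else runif(1, 1.6, 5)
  C_max <- 10^runif(1, -5, -3)
  alpha_max <- runif(1, 10, 80)           # n K C^(n-1) at the top of the grid
  K <- alpha_max / (n * C_max^(n - 1))
  span <- (1e-5 / alpha_max)^(1 / (n - 1)) # alpha at C_min about 1e-5
  C <- exp(seq(log(C_max * span), log(C_max), length.out = 30))
  list(model = aggregation_model(n, K, eps1, epsn, 1), C = C)
}

# A small flat-topped synthetic spectrum for the IO tests.
flat_spectrum <- function(value = 1, lo = 400, hi = 500, by = 1) {
  wl <- seq(lo, hi, by = by)
  dye_spectrum(wl, rep(value, length(wl)))
}
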