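stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

check_aggregation_number <- function(n) {
  if (!is_count(n) || n < 2)
    stopf("aggregation number must be an integer >= 2, got %s",
          paste(format(n), collapse = ", "))
  as.integer(n)
}

## Exact non-negative least squares for a small number of regressors.
## The NNLS optimum restricted to its support equals the unconstrained
## least-squares solution on that support, so enumerating all supports and
## keeping the feasible solution with minimal RSS is exact. Only intended
## for a handful of columns (here: two).
nnls_small <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 8) stopf("nnls_small is for small designs (got %d columns)", p)
  best_coef <- rep(0, p)
  best_rss <- sum(y^2)
  for (mask in seq_len(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    Xs <- X[, free, drop = FALSE]
    beta <- tryCatch(qr.coef(qr(Xs), y), error = function(e) NULL)
    if (is.null(beta) || anyNA(beta) || any(beta < 0)) next
    rss <- sum((y - Xs %*% beta)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_coef <- rep(0, p)
      best_coef[free] <- beta
    }
  }
  list(coefficients = best_coef, rss = best_rss)
}

## Least-squares slope of a through-origin line y = s x.
slope_through_origin <- function(x, y) sum(x * y) / sum(x^2)

## Local smoother that preserves polynomial trends up to degree 2 exactly
## (a plain moving average would bias the curvature, and the smoothed slope
## estimator differentiates a fitted parabola): Savitzky-Golay, quadratic,
## 5-point frame.
smooth_local <- function(y) {
  if (length(y) < 5) return(y)
  as.numeric(signal::sgolayfilt(y, p = 2, n = 5))
}

## 1-D minimization by successive grid zooming: evaluate on an equispaced
## grid, keep the best point's neighbourhood, repeat until the bracket is
## narrower than tol. Slower than golden-section search but immune to the
## kinks (active-set switches, point drops) and needle-sharp minima of the
## profiled reconstruction residual.
zoom_minimize <- function(obj, lo, hi, tol, k = 21) {
  repeat {
    xs <- seq(lo, hi, length.out = k)
    fs <- vapply(xs, obj, numeric(1))
    j <- which.min(fs)
    lo2 <- xs[max(1L, j - 1L)]
    hi2 <- xs[min(k, j + 1L)]
    if ((hi2 - lo2) <= tol || fs[j] == 0)
      return(list(minimum = xs[j], objective = fs[j]))
    lo <- lo2
    hi <- hi2
  }
}

## Geometric (log-spaced) concentration grid, the shape of a serial dilution.
geom_grid <- function(lo, hi, length.out) {
  exp(seq(log(lo), log(hi), length.out = length.out))
}
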