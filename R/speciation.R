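#' Aggregation equilibrium model
#'
#' Physical parameter set of the single equilibrium
#' \eqn{nD \rightleftharpoons D_n} with distinct monomer and aggregate
#' integral extinction coefficients.
#'
#' @param n Aggregation number, integer >= 2.
#' @param K_n Equilibrium constant \eqn{K_n = C_n / C_1^n} in
#'   \eqn{M^{1-n}}, positive.
#' @param eps1 Monomer integral extinction coefficient (AU nm / M / cm),
#'   non-negative.
#' @param epsn Aggregate integral extinction coefficient, non-negative and
#'   different from `eps1` (a degenerate pair carries no excess signal).
#' @param path_length Path length in cm.
#' @return An object of class `aggregation_model`.
#' @export
aggregation_model <- function(n, K_n, eps1, epsn, path_length = 1) {
  n <- check_aggregation_number(n)
  if (!is.numeric(K_n) || length(K_n) != 1 || !is.finite(K_n) || K_n <= 0)
    stopf("K_n must be a single positive number")
  if (eps1 < 0 || epsn < 0) stopf("extinction coefficients must be >= 0")
  if (eps1 == epsn)
    stopf("eps1 and epsn must differ (the excess absorbance vanishes otherwise)")
  if (path_length <= 0) stopf("path_length must be positive")
  structure(list(n = n, K_n = as.numeric(K_n), eps1 = as.numeric(eps1),
                 epsn = as.numeric(epsn), path_length = as.numeric(path_length)),
            class = "aggregation_model")
}

#' @export
print.aggregation_model <- function(x, ...) {
  cat(sprintf("<aggregation_model: n=%d, K_n=%.4g M^%d, eps1=%.4g, epsn=%.4g, l=%g cm>\n",
              x$n, x$K_n, 1L - x$n, x$eps1, x$epsn, x$path_length))
  invisible(x)
}

## Root of f(xi) = alpha xi^n + xi - 1 on (0, 1], where alpha = n K C^(n-1).
## f(0+) = -1 < 0, f(1) = alpha > 0 and f' > 0 on (0,1), so the root is
## unique and bracketed. Brent via uniroot, then Newton polishing to bring
## the residual to machine precision. For very large alpha the substituted
## variable u = alpha xi^n in (0,1) avoids overflow.
solve_xi_scalar <- function(n, alpha) {
  if (!is.finite(alpha)) stopf("polynomial coefficient overflowed")
  if (alpha <= 1e12) {
    xi <- stats::uniroot(function(x) alpha * x^n + x - 1,
                         lower = 1e-16, upper = 1,
                         f.lower = -1 + 1e-16, f.upper = alpha,
                         tol = 1e-14)$root
    for (i in 1:3) {
      fx <- alpha * xi^n + xi - 1
      xi <- xi - fx / (n * alpha * xi^(n - 1) + 1)
      if (xi <= 0) xi <- .Machine$double.xmin
      if (xi > 1) xi <- 1
    }
  } else {
    la <- log(alpha)
    g <- function(u) u + exp((log(u) - la) / n) - 1
    u <- stats::uniroot(g, lower = 1e-300, upper = 1, tol = 1e-15)$root
    for (i in 1:3) {
      t <- exp((log(u) - la) / n)
      u <- u - (u + t - 1) / (1 + t / (n * u))
      if (u <= 0) u <- .Machine$double.xmin
    }
    xi <- exp((log(u) - la) / n)
  }
  min(max(xi, .Machine$double.xmin), 1)
}

#' Monomer fraction of the aggregation equilibrium
#'
#' Solves \eqn{(n K_n C^{n-1})\,\xi^n + \xi - 1 = 0} for the monomer
#' fraction \eqn{\xi = C_1/C}, the unique root in (0, 1]. As
#' \eqn{C \to 0} the fraction tends to 1 (pure monomer).
#'
#' @param n Aggregation number (integer >= 2).
#' @param K_n Equilibrium constant in \eqn{M^{1-n}}, positive.
#' @param C_total Total concentration(s) in mol/L, positive; vectorized.
#' @return Numeric vector of monomer fractions in (0, 1].
#' @export
solve_monomer_fraction <- function(n, K_n, C_total) {
  n <- check_aggregation_number(n)
  if (!is.numeric(K_n) || length(K_n) != 1 || K_n <= 0)
    stopf("K_n must be a single positive number")
  if (any(!is.finite(C_total)) || any(C_total <= 0))
    stopf("C_total must be positive and finite")
  vapply(C_total, function(C) solve_xi_scalar(n, n * K_n * C^(n - 1)),
         numeric(1))
}

#' Speciation: monomer and aggregate concentrations
#'
#' For each total concentration, solves the monomer fraction and returns the
#' species concentrations linked by the material balance
#' \eqn{C = C_1 + n C_n} (which holds by construction).
#'
#' @param model An [aggregation_model()].
#' @param C_totals Total concentrations in mol/L, positive.
#' @return A data frame with columns `C_total`, `xi`, `C1`, `Cn`.
#' @export
speciate <- function(model, C_totals) {
  stopifnot(inherits(model, "aggregation_model"))
  n <- model$n
  xi <- solve_monomer_fraction(n, model$K_n, C_totals)
  C1 <- xi * C_totals
  ## Cn from the equilibrium law K C1^n (in log space to dodge over/underflow)
  ## rather than (C - C1)/n, which cancels catastrophically when xi ~ 1. The
  ## polished root makes the material balance hold to machine precision
  ## either way: C1 + n Cn - C = C * f(xi).
  la <- log(n) + log(model$K_n) + (n - 1) * log(C_totals)
  Cn <- C_totals / n * exp(la + n * log(xi))
  data.frame(C_total = C_totals, xi = xi, C1 = C1, Cn = Cn)
}

#' Predicted integral absorbance of the two-species model
#'
#' \eqn{\bar{A} = \bar\epsilon_1 \ell C_1 + n \bar\epsilon_n \ell C_n}.
#' The slope at infinite dilution equals \eqn{\bar\epsilon_1 \ell}, which is
#' what anchors the excess-absorbance reference state.
#'
#' @inheritParams speciate
#' @return Numeric vector of integral absorbances (AU nm).
#' @export
predict_integral_absorbance <- function(model, C_totals) {
  sp <- speciate(model, C_totals)
  model$eps1 * model$path_length * sp$C1 +
    model$n * model$epsn * model$path_length * sp$Cn
}
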