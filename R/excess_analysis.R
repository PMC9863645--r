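#' Limiting slope of the absorbance curve at infinite dilution
#'
#' Estimates the reference-state slope \eqn{\bar\epsilon_1 \ell} (monomer
#' integral extinction coefficient times path length) from the
#' lowest-concentration points of an absorbance curve. Two estimators are
#' offered:
#'
#' * `"linear3"`: through-origin least-squares line on the three lowest
#'   points (the physically forced intercept is \eqn{\bar{A}(0) = 0});
#' * `"smooth5"`: the curve is smoothed with a quadratic-preserving
#'   Savitzky-Golay filter (degree 2, 5-point frame), then a through-origin
#'   quadratic
#'   \eqn{\bar{A} = p_1 C + p_2 C^2} is fitted to the five lowest smoothed
#'   points and \eqn{p_1} (the derivative at C = 0) is returned. Intended
#'   for rough curves.
#'
#' Both are consistent only if the lowest concentrations are effectively in
#' the dilute (monomer) regime; see [fit_aggregation()]'s `refine_slope` for
#' the self-consistent correction applied when they are not.
#'
#' @param curve An [absorbance_curve()] with at least 3 (`linear3`) or
#'   5 (`smooth5`) points.
#' @param method `"linear3"` or `"smooth5"`.
#' @return An object of class `limiting_slope` with fields `eps1_ell`
#'   (AU nm / M), `method`, `points_used`.
#' @export
limiting_slope <- function(curve, method = c("linear3", "smooth5")) {
  stopifnot(inherits(curve, "absorbance_curve"))
  method <- match.arg(method)
  C <- curve$concentrations
  A <- curve$integral_absorbance
  if (method == "linear3") {
    if (length(C) < 3) stopf("linear3 needs >= 3 points, got %d", length(C))
    s <- slope_through_origin(C[1:3], A[1:3])
    used <- 3L
  } else {
    if (length(C) < 5) stopf("smooth5 needs >= 5 points, got %d", length(C))
    As <- smooth_local(A)
    beta <- qr.coef(qr(cbind(C[1:5], C[1:5]^2)), As[1:5])
    s <- beta[[1]]
    used <- 5L
  }
  if (!is.finite(s) || s <= 0)
    stopf("limiting slope is not positive (%.4g): no monomer absorbance signal", s)
  structure(list(eps1_ell = s, method = method, points_used = used),
            class = "limiting_slope")
}

#' @export
print.limiting_slope <- function(x, ...) {
  cat(sprintf("<limiting_slope: eps1*l = %.6g AU nm/M (%s, %d points)>\n",
              x$eps1_ell, x$method, x$points_used))
  invisible(x)
}

## Raw excess, curvature call, rectification and dropping in one quiet
## internal step shared by the public op and the slope-refinement loop.
## Returns NULL when no usable signal remains.
excess_raw <- function(C, A, eps1_ell) {
  raw <- A - eps1_ell * C
  total <- sum(raw)
  if (total == 0 && all(raw == 0)) return(NULL)
  flipped <- total < 0
  omega <- if (flipped) -raw else raw
  keep <- omega > 0
  if (!any(keep)) return(NULL)
  list(concentrations = C[keep], omega = omega[keep],
       curvature = if (flipped) "concave" else "convex",
       sign_flipped = flipped, n_dropped = sum(!keep))
}

#' Excess absorbance curve
#'
#' Subtracts the Lambert-Beer reference anchored at the limiting slope:
#' \eqn{\Omega(C) = \bar{A}_{exp}(C) - \bar\epsilon_1 \ell C}. The curvature
#' of the absorbance curve is classified from the sign of the summed raw
#' excess: predominantly negative means a concave curve
#' (\eqn{\bar\epsilon_1 > \bar\epsilon_n}) and all values are negated so the
#' stored \eqn{\Omega} is positive. Points whose rectified excess is not
#' positive (noise at extreme dilution) are dropped with a message.
#'
#' @param curve An [absorbance_curve()].
#' @param slope A [limiting_slope()] or a single positive number
#'   (\eqn{\bar\epsilon_1 \ell} in AU nm / M).
#' @return An object of class `excess_curve` with fields `concentrations`,
#'   `omega` (> 0), `curvature` (`"concave"` or `"convex"`), `sign_flipped`,
#'   `eps1_ell`, `path_length`, `n_dropped`.
#' @export
excess_absorbance <- function(curve, slope) {
  stopifnot(inherits(curve, "absorbance_curve"))
  eps1_ell <- if (inherits(slope, "limiting_slope")) slope$eps1_ell else slope
  if (!is.numeric(eps1_ell) || length(eps1_ell) != 1 || eps1_ell <= 0)
    stopf("slope must be a limiting_slope or a single positive number")
  ex <- excess_raw(curve$concentrations, curve$integral_absorbance, eps1_ell)
  if (is.null(ex))
    stopf("no usable excess signal (absorbance is Lambert-Beer within this slope)")
  if (ex$n_dropped > 0)
    message(sprintf("dropped %d point(s) with non-positive rectified excess",
                    ex$n_dropped))
  structure(c(ex, list(eps1_ell = eps1_ell, path_length = curve$path_length)),
            class = "excess_curve")
}

#' @export
print.excess_curve <- function(x, ...) {
  cat(sprintf("<excess_curve: %d points, %s%s, eps1*l = %.4g>\n",
              length(x$omega), x$curvature,
              if (x$sign_flipped) " (sign-flipped)" else "", x$eps1_ell))
  invisible(x)
}

#' Export an excess curve as delimited text
#'
#' Header comments record the reference slope and rectification state;
#' columns are `C,omega`.
#'
#' @param excess An [excess_absorbance()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_excess_curve <- function(excess, path) {
  stopifnot(inherits(excess, "excess_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# eps1_ell %.15g", excess$eps1_ell),
               sprintf("# curvature %s", excess$curvature),
               sprintf("# sign_flipped %s", excess$sign_flipped),
               "concentration_M,omega_AU_nm"), con)
  utils::write.table(cbind(excess$concentrations, excess$omega), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
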