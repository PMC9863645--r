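#' Non-negative least-squares fit of the key equation at fixed n
#'
#' Fits \eqn{C = a\,\Omega + b\,\Omega^{1/n}} with \eqn{a, b \ge 0} by exact
#' active-set non-negative least squares. Residuals (and the RMSE) are in
#' concentration units.
#'
#' @param excess An [excess_absorbance()] result with at least 3 points.
#' @param n Candidate aggregation number (integer >= 2).
#' @return An object of class `fit_candidate`: `n`, `a`, `b`, `rmse`.
#' @export
fit_for_n <- function(excess, n) {
  stopifnot(inherits(excess, "excess_curve"))
  n <- check_aggregation_number(n)
  m <- length(excess$omega)
  if (m < 3) stopf("need at least 3 usable excess points, got %d", m)
  fit <- nnls_small(cbind(excess$omega, excess$omega^(1 / n)),
                    excess$concentrations)
  structure(list(n = n, a = fit$coefficients[1], b = fit$coefficients[2],
                 rmse = sqrt(fit$rss / m)),
            class = "fit_candidate")
}

#' @export
print.fit_candidate <- function(x, ...) {
  cat(sprintf("<fit_candidate: n=%d, a=%.4g, b=%.4g, rmse=%.4g M>\n",
              x$n, x$a, x$b, x$rmse))
  invisible(x)
}

#' Scan candidate aggregation numbers by RMSE
#'
#' Fits the key equation for every integer n in `[n_min, n_max]` and selects
#' the candidate with minimal RMSE; ties break toward smaller n (parsimony).
#' A relative gap below 5% between the best and second-best RMSE triggers a
#' warning, since near-ties make the selected n uncertain.
#'
#' @param excess An [excess_absorbance()] result.
#' @param n_min,n_max Scan range (integers, `2 <= n_min <= n_max`).
#' @return An object of class `fit_scan`: `candidates` (list of
#'   [fit_for_n()] results), `selected`, `runner_up_gap`.
#' @export
scan_n <- function(excess, n_min = 2, n_max = 10) {
  n_min <- check_aggregation_number(n_min)
  n_max <- check_aggregation_number(n_max)
  if (n_max < n_min) stopf("n_max (%d) < n_min (%d)", n_max, n_min)
  if (length(excess$omega) < 3)
    stopf("need at least 3 usable excess points, got %d", length(excess$omega))
  candidates <- lapply(n_min:n_max, function(n) fit_for_n(excess, n))
  new_fit_scan(candidates)
}

## Assemble a fit_scan from per-n candidates (shared with the refined scan).
new_fit_scan <- function(candidates) {
  rmse <- vapply(candidates, `[[`, numeric(1), "rmse")
  sel <- which.min(rmse)  # first minimum = smallest n on ties
  gap <- if (length(rmse) > 1) {
    second <- min(rmse[-sel])
    if (rmse[sel] > 0) (second - rmse[sel]) / rmse[sel] else Inf
  } else Inf
  if (is.finite(gap) && gap < 0.05)
    warnf("RMSE minimum at n=%d is nearly tied (runner-up gap %.1f%%): the selected n is uncertain",
          candidates[[sel]]$n, 100 * gap)
  structure(list(candidates = candidates, selected = candidates[[sel]],
                 runner_up_gap = gap),
            class = "fit_scan")
}

#' @export
print.fit_scan <- function(x, ...) {
  tab <- data.frame(n = vapply(x$candidates, `[[`, integer(1), "n"),
                    rmse = vapply(x$candidates, `[[`, numeric(1), "rmse"))
  cat("<fit_scan>\n")
  print(tab, row.names = FALSE)
  cat(sprintf("selected n = %d (runner-up gap %.2g)\n",
              x$selected$n, x$runner_up_gap))
  invisible(x)
}

#' Physical parameters from the fitted coefficients
#'
#' Inverts the key-equation coefficients: \eqn{\Delta_n = 1/a} and
#' \eqn{K_n = a / (n b^n)} (from \eqn{a = 1/\Delta_n},
#' \eqn{b = (n K_n \Delta_n)^{-1/n}}). The aggregate coefficient follows
#' from the curvature: \eqn{\bar\epsilon_n = \bar\epsilon_1 - \Delta_n/\ell}
#' for a concave absorbance curve, \eqn{+\Delta_n/\ell} for a convex one; a
#' negative result is floored at zero with a warning.
#'
#' @param candidate A [fit_for_n()] result with both coefficients active
#'   (`a > 0`, `b > 0`).
#' @param slope A [limiting_slope()] (or the numeric \eqn{\bar\epsilon_1 \ell}).
#' @param path_length Path length in cm.
#' @param curvature `"concave"` or `"convex"` (from the excess curve).
#' @return An [aggregation_model()] with attribute `delta_n`
#'   (\eqn{|\bar\epsilon_1-\bar\epsilon_n| \ell}, AU nm / M).
#' @export
extract_parameters <- function(candidate, slope, path_length, curvature) {
  stopifnot(inherits(candidate, "fit_candidate"))
  curvature <- match.arg(curvature, c("concave", "convex"))
  eps1_ell <- if (inherits(slope, "limiting_slope")) slope$eps1_ell else slope
  if (candidate$a <= 0 || candidate$b <= 0)
    stopf("model degenerate for this n (a=%.3g, b=%.3g): both regressors must be active",
          candidate$a, candidate$b)
  delta_n <- 1 / candidate$a
  K_n <- candidate$a / (candidate$n * candidate$b^candidate$n)
  eps1 <- eps1_ell / path_length
  epsn <- if (curvature == "concave") eps1 - delta_n / path_length
          else eps1 + delta_n / path_length
  if (epsn < 0) {
    warnf("extracted aggregate coefficient is negative (%.4g); floored at 0", epsn)
    epsn <- 0
  }
  model <- aggregation_model(candidate$n, K_n, eps1, epsn, path_length)
  attr(model, "delta_n") <- delta_n
  model
}

#' Reliability reconstruction of the absorbance curve
#'
#' Self-consistency check of a fitted model: for every measured
#' concentration the monomer-fraction polynomial is solved, the species
#' concentrations are formed, and the integral absorbance is recomputed
#' from the model. The through-origin regression slope of the reconstructed
#' against the measured absorbance (1 for a perfect model) and the maximum
#' relative deviation summarize the agreement.
#'
#' @param model An [aggregation_model()] (typically from
#'   [extract_parameters()]).
#' @param curve The measured [absorbance_curve()].
#' @return An object of class `reliability_result`: `points` (speciation
#'   data frame), `A_calc`, `slope_calc_vs_exp`, `max_rel_dev`.
#' @export
reliability_check <- function(model, curve) {
  stopifnot(inherits(model, "aggregation_model"),
            inherits(curve, "absorbance_curve"))
  sp <- speciate(model, curve$concentrations)
  A_calc <- model$eps1 * model$path_length * sp$C1 +
    model$n * model$epsn * model$path_length * sp$Cn
  A_exp <- curve$integral_absorbance
  structure(list(points = sp, A_calc = A_calc,
                 slope_calc_vs_exp = slope_through_origin(A_exp, A_calc),
                 max_rel_dev = max(abs(A_calc - A_exp) / abs(A_exp))),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability: A_calc = %.4f * A_exp, max relative deviation %.3g>\n",
              x$slope_calc_vs_exp, x$max_rel_dev))
  invisible(x)
}

#' Bootstrap confidence interval for the equilibrium constant
#'
#' Case-resampling bootstrap over the (Omega, C) pairs at a fixed
#' aggregation number: each replicate refits the key equation and
#' re-extracts \eqn{K_n = a/(n b^n)}. Replicates with a degenerate fit
#' (an inactive coefficient) are discarded; more than 20% discarded is an
#' error. Deterministic under a fixed seed.
#'
#' @param excess An [excess_absorbance()] result.
#' @param n Aggregation number (post-selection).
#' @param n_boot Number of replicates (>= 50).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95, i.e. the 2.5/97.5 percentile
#'   interval).
#' @return Named numeric `c(lo, hi)` with attributes `K_boot` (the replicate
#'   values) and `n_discarded`.
#' @export
bootstrap_K <- function(excess, n, n_boot = 200, seed = NULL, conf = 0.95) {
  stopifnot(inherits(excess, "excess_curve"))
  n <- check_aggregation_number(n)
  if (!is_count(n_boot) || n_boot < 50) stopf("n_boot must be an integer >= 50")
  m <- length(excess$omega)
  one_rep <- function(idx) {
    om <- excess$omega[idx]
    C <- excess$concentrations[idx]
    if (length(unique(om)) < 2) return(NA_real_)
    fit <- nnls_small(cbind(om, om^(1 / n)), C)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    if (a <= 0 || b <= 0) return(NA_real_)
    a / (n * b^n)
  }
  draw <- function() {
    vapply(seq_len(n_boot), function(i) one_rep(sample.int(m, m, replace = TRUE)),
           numeric(1))
  }
  K_boot <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bad <- sum(is.na(K_boot))
  if (bad > 0.2 * n_boot)
    stopf("bootstrap unstable: %d/%d replicates had degenerate fits", bad, n_boot)
  ci <- stats::quantile(K_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(c(lo = ci[1], hi = ci[2]), K_boot = K_boot, n_discarded = bad)
}

## ---- slope refinement ------------------------------------------------------

## Reconstruction residual of the full forward model at reference slope s
## and candidate n: excess -> NNLS -> (K, Delta) -> speciation -> A_calc.
## Returns a large penalty when the fit degenerates so the 1-D optimizer
## stays quiet and inside the feasible region.
recon_rss <- function(C, A, s, n, path_length) {
  penalty <- sum(A^2) * 1e6
  ex <- excess_raw(C, A, s)
  if (is.null(ex) || length(ex$omega) < 3) return(penalty)
  fit <- nnls_small(cbind(ex$omega, ex$omega^(1 / n)), ex$concentrations)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (a <= 0 || b <= 0) return(penalty)
  K <- a / (n * b^n)
  delta <- 1 / a
  eps1 <- s / path_length
  epsn_ell <- if (ex$sign_flipped) s - delta else s + delta
  xi <- vapply(C, function(cc) solve_xi_scalar(n, n * K * cc^(n - 1)), numeric(1))
  C1 <- xi * C
  Cn <- (C - C1) / n
  A_calc <- s * C1 + n * epsn_ell * Cn
  sum((A_calc - A)^2)
}

## Per-candidate-n refinement of the reference slope: the slope is a nuisance
## parameter profiled by minimizing the reconstruction residual within a
## bracket around the direct estimate. Selection across n still uses the
## key-equation RMSE, which the true n drives to zero for noiseless data.
scan_n_refined <- function(curve, slope0, n_min, n_max) {
  C <- curve$concentrations
  A <- curve$integral_absorbance
  pl <- curve$path_length
  s0 <- slope0$eps1_ell
  bracket <- s0 * c(0.6, 1.4)
  per_n <- lapply(n_min:n_max, function(n) {
    obj <- function(s) recon_rss(C, A, s, n, pl)
    s <- zoom_minimize(obj, bracket[1], bracket[2], tol = s0 * 1e-8)$minimum
    ex <- excess_raw(C, A, s)
    if (is.null(ex) || length(ex$omega) < 3)
      return(list(candidate = structure(list(n = n, a = 0, b = 0, rmse = Inf),
                                        class = "fit_candidate"),
                  slope = s, excess = ex))
    fit <- nnls_small(cbind(ex$omega, ex$omega^(1 / n)), ex$concentrations)
    cand <- structure(list(n = n, a = fit$coefficients[1],
                           b = fit$coefficients[2],
                           rmse = sqrt(fit$rss / length(ex$omega))),
                      class = "fit_candidate")
    list(candidate = cand, slope = s, excess = ex)
  })
  scan <- new_fit_scan(lapply(per_n, `[[`, "candidate"))
  sel <- which(vapply(per_n, function(p) p$candidate$n, integer(1)) ==
                 scan$selected$n)
  at_edge <- abs(per_n[[sel]]$slope - bracket) / s0 < 0.01
  if (any(at_edge))
    warnf("refined slope hit the search bracket edge; estimate may be unreliable")
  list(scan = scan, slope = per_n[[sel]]$slope, excess = per_n[[sel]]$excess)
}

## ---- pipeline --------------------------------------------------------------

#' Fit the aggregation equilibrium from spectra or an absorbance curve
#'
#' Full analysis pipeline: band integration (for a spectral series),
#' limiting-slope estimation, excess-absorbance rectification, the
#' non-negative least-squares scan over aggregation numbers, parameter
#' extraction and the reliability reconstruction. The first failing stage
#' aborts with its name.
#'
#' With `refine_slope = TRUE` (the default) the reference slope is treated
#' as a nuisance parameter: for every candidate n it is re-optimized by
#' minimizing the reliability-reconstruction residual, and the scan then
#' compares candidates at their own refined slopes. This corrects the
#' deterministic bias of the direct estimators when the lowest measured
#' concentrations still contain aggregate, which otherwise distorts the
#' selected n (see the package vignette).
#'
#' @param x A [spectral_series()] or an [absorbance_curve()].
#' @param ... Passed between methods.
#' @param window A [band_window()] (spectral series method only).
#' @param slope_method `"linear3"` or `"smooth5"` (see [limiting_slope()]).
#' @param refine_slope Refine the reference slope per candidate n
#'   (default `TRUE`).
#' @param n_min,n_max Aggregation-number scan range.
#' @param n_boot Bootstrap replicates for the K confidence interval
#'   (0 skips the bootstrap).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level for the bootstrap interval.
#' @return An object of class `aggregation_fit`: fields `model`
#'   ([aggregation_model()]), `scan` ([scan_n()] result), `slope`
#'   ([limiting_slope()], refined if requested), `excess`, `reliability`,
#'   `K_ci`, `curve`, `warnings`.
#' @examples
#' sc <- dye_preset("fs_upw", noise_rel = 0, seed = 1)
#' fit <- fit_aggregation(generate_curve(sc))
#' fit$model$n          # 3: the trimer
#' @export
fit_aggregation <- function(x, ...) UseMethod("fit_aggregation")

#' @rdname fit_aggregation
#' @export
fit_aggregation.spectral_series <- function(x, window, ...) {
  if (missing(window) || !inherits(window, "band_window"))
    stopf("stage 'band integration' failed: a band_window is required")
  curve <- run_stage("band integration", to_absorbance_curve(x, window))
  fit_aggregation(curve, ...)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' @rdname fit_aggregation
#' @export
fit_aggregation.absorbance_curve <- function(x, slope_method = c("linear3", "smooth5"),
                                             refine_slope = TRUE,
                                             n_min = 2, n_max = 10,
                                             n_boot = 0, seed = NULL,
                                             conf = 0.95, ...) {
  slope_method <- match.arg(slope_method)
  warnings_seen <- character()
  note <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  slope0 <- run_stage("limiting slope", limiting_slope(x, slope_method))

  if (refine_slope) {
    ref <- run_stage("slope refinement / n scan",
                     note(scan_n_refined(x, slope0, n_min, n_max)))
    scan <- ref$scan
    slope <- structure(list(eps1_ell = ref$slope,
                            method = paste0(slope_method, "+refined"),
                            points_used = length(x$concentrations)),
                       class = "limiting_slope")
    excess <- structure(c(ref$excess,
                          list(eps1_ell = ref$slope,
                               path_length = x$path_length)),
                        class = "excess_curve")
  } else {
    slope <- slope0
    excess <- run_stage("excess absorbance",
                        suppressMessages(excess_absorbance(x, slope)))
    scan <- run_stage("n scan", note(scan_n(excess, n_min, n_max)))
  }

  model <- run_stage("parameter extraction",
                     note(extract_parameters(scan$selected, slope,
                                             x$path_length, excess$curvature)))
  reliability <- run_stage("reliability check", reliability_check(model, x))
  K_ci <- if (n_boot > 0)
    run_stage("bootstrap", bootstrap_K(excess, model$n, n_boot, seed, conf))
  else NULL

  structure(list(model = model, scan = scan, slope = slope, excess = excess,
                 reliability = reliability, K_ci = K_ci, curve = x,
                 warnings = warnings_seen),
            class = "aggregation_fit")
}

#' @export
print.aggregation_fit <- function(x, ...) {
  cat("Aggregation equilibrium fit (excess absorbance)\n")
  cat(sprintf("  selected n      : %d\n", x$model$n))
  cat(sprintf("  K_n             : %.4g M^%d\n", x$model$K_n, 1L - x$model$n))
  cat(sprintf("  eps1 (monomer)  : %.4g AU nm/(M cm)\n", x$model$eps1))
  cat(sprintf("  epsn (aggregate): %.4g AU nm/(M cm)\n", x$model$epsn))
  cat(sprintf("  delta_n         : %.4g AU nm/M\n", attr(x$model, "delta_n")))
  cat(sprintf("  curvature       : %s\n", x$excess$curvature))
  cat(sprintf("  slope method    : %s\n", x$slope$method))
  cat(sprintf("  reliability     : A_calc = %.4f A_exp (max rel dev %.3g)\n",
              x$reliability$slope_calc_vs_exp, x$reliability$max_rel_dev))
  if (!is.null(x$K_ci))
    cat(sprintf("  K bootstrap CI  : [%.4g, %.4g]\n", x$K_ci[["lo"]], x$K_ci[["hi"]]))
  if (length(x$warnings))
    cat("  warnings        :", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Structured report of an aggregation fit
#'
#' @param fit An [fit_aggregation()] result.
#' @return A plain list ready for JSON serialization: the RMSE scan, the
#'   selected parameters, the reliability summary, the optional bootstrap
#'   interval and any warnings.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "aggregation_fit"))
  list(n_scan = data.frame(
         n = vapply(fit$scan$candidates, `[[`, integer(1), "n"),
         rmse = vapply(fit$scan$candidates, `[[`, numeric(1), "rmse")),
       selected_n = fit$model$n,
       K_n = fit$model$K_n,
       delta_n = attr(fit$model, "delta_n"),
       eps1 = fit$model$eps1,
       epsn = fit$model$epsn,
       curvature = fit$excess$curvature,
       slope_method = fit$slope$method,
       slope_calc_vs_exp = fit$reliability$slope_calc_vs_exp,
       max_rel_dev = fit$reliability$max_rel_dev,
       K_ci = if (!is.null(fit$K_ci)) as.list(fit$K_ci) else NULL,
       warnings = fit$warnings)
}

#' Write a fit report as JSON (atomically)
#'
#' @param fit An [fit_aggregation()] result.
#' @param path Output path; written via a temporary file and rename.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(fit_report(fit), tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  file.rename(tmp, path)
  invisible(path)
}
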