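make_excess <- function(C, omega, curvature = "convex") {
  structure(list(concentrations = C, omega = omega, curvature = curvature,
                 sign_flipped = curvature == "concave", eps1_ell = 1,
                 path_length = 1, n_dropped = 0L),
            class = "excess_curve")
}

test_that("the key-equation fit inverts its own generating coefficients", {
  omega <- seq(0.1, 2, length.out = 12)
  C <- 2 * omega + 3 * omega^(1 / 3)
  fit <- fit_for_n(make_excess(C, omega), 3)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 3, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-12)

  # a misspecified n pays in RMSE
  fit2 <- fit_for_n(make_excess(C, omega), 2)
  expect_gt(fit2$rmse, fit$rmse + 1e-6)
})

test_that("non-negativity constraints activate cleanly", {
  omega <- seq(0.1, 2, length.out = 10)
  C <- pmax(-omega + omega^(1 / 2), 1e-3)   # would want a < 0
  fit <- fit_for_n(make_excess(C, omega), 2)
  expect_equal(fit$a, 0)
  expect_gt(fit$rmse, 0)

  expect_error(fit_for_n(make_excess(c(1, 2), c(0.1, 0.2)), 2), "at least 3")
})

test_that("the active-set NNLS matches a dense grid-search oracle", {
  set.seed(31)
  for (i in 1:8) {
    m <- sample(4:10, 1)
    omega <- sort(runif(m, 0.05, 2))
    n <- sample(2:5, 1)
    a0 <- runif(1, 0, 3); b0 <- runif(1, 0, 3)
    C <- a0 * omega + b0 * omega^(1 / n) + rnorm(m, 0, 0.05)
    C <- pmax(C, 1e-3)
    X <- cbind(omega, omega^(1 / n))
    fit <- fit_for_n(make_excess(C, omega), n)
    oracle <- grid_nnls(X, C, a_hi = 2 * a0 + 2, b_hi = 2 * b0 + 2, k = 400)
    # the analytic optimum can only be at least as good as the grid optimum
    rss_fit <- sum((C - fit$a * omega - fit$b * omega^(1 / n))^2)
    expect_lte(rss_fit, oracle[["rss"]] + 1e-10)
    grid_step <- max(2 * a0 + 2, 2 * b0 + 2) / 400
    expect_lt(abs(fit$a - oracle[["a"]]), 2 * grid_step)
    expect_lt(abs(fit$b - oracle[["b"]]), 2 * grid_step)
  }
})

test_that("the RMSE scan selects the generating n and reports near-ties", {
  omega <- seq(0.05, 1.5, length.out = 15)
  C <- 0.5 * omega + 2 * omega^(1 / 4)
  scan <- scan_n(make_excess(C, omega), 2, 8)
  expect_equal(scan$selected$n, 4L)
  expect_equal(vapply(scan$candidates, `[[`, integer(1), "n"), 2:8)
  expect_equal(min(vapply(scan$candidates, `[[`, numeric(1), "rmse")),
               scan$selected$rmse)

  expect_error(scan_n(make_excess(c(1, 2), c(0.1, 0.2)), 2, 5), "at least 3")
  expect_error(scan_n(make_excess(C, omega), 5, 3), "n_max")
})

test_that("parameter extraction inverts the key equation", {
  cand <- structure(list(n = 3L, a = 2, b = 3, rmse = 0),
                    class = "fit_candidate")
  m <- extract_parameters(cand, slope = 1, path_length = 1,
                          curvature = "convex")
  expect_equal(attr(m, "delta_n"), 0.5)
  expect_equal(m$K_n, 2 / 81, tolerance = 1e-12)
  expect_equal(m$epsn, 1 + 0.5)

  # fluorescein-water printed coefficients: delta_3 = 0.241 - 0.027
  cand_fs <- structure(list(n = 3L, a = 1 / 0.214, b = 1, rmse = 0),
                       class = "fit_candidate")
  m_fs <- extract_parameters(cand_fs, slope = 0.241, path_length = 1,
                             curvature = "concave")
  expect_equal(attr(m_fs, "delta_n"), 0.214, tolerance = 1e-12)
  expect_equal(m_fs$epsn, 0.027, tolerance = 1e-10)

  cand0 <- structure(list(n = 3L, a = 0, b = 3, rmse = 1),
                     class = "fit_candidate")
  expect_error(extract_parameters(cand0, 1, 1, "convex"), "degenerate")
})

test_that("extraction and the key equation round-trip to 1e-9", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    a0 <- runif(1, 0.2, 5)
    b0 <- runif(1, 0.2, 5)
    omega <- sort(runif(12, 0.01, 3))
    C <- a0 * omega + b0 * omega^(1 / n)
    fit <- fit_for_n(make_excess(C, omega), n)
    m <- extract_parameters(fit, slope = 10, path_length = 1,
                            curvature = "convex")
    # regenerate the curve through K and Delta and refit
    a_back <- 1 / attr(m, "delta_n")
    b_back <- (n * m$K_n * attr(m, "delta_n"))^(-1 / n)
    expect_equal(a_back, fit$a, tolerance = 1e-9)
    expect_equal(b_back, fit$b, tolerance = 1e-9)
    C_back <- a_back * omega + b_back * omega^(1 / n)
    fit2 <- fit_for_n(make_excess(C_back, omega), n)
    expect_equal(fit2$a, fit$a, tolerance = 1e-9)
    expect_equal(fit2$b, fit$b, tolerance = 1e-9)
  }
})

test_that("reliability reconstruction is exact for the true model", {
  m <- aggregation_model(3, 1.4e9, 0.241, 0.027, 1)
  C <- exp(seq(log(0.518e-6), log(133e-6), length.out = 24))
  cv <- model_curve(m, C)
  rel <- reliability_check(m, cv)
  expect_equal(rel$slope_calc_vs_exp, 1, tolerance = 1e-9)
  expect_lt(rel$max_rel_dev, 1e-6)
  expect_equal(rel$points$C1 + 3 * rel$points$Cn, C, tolerance = 1e-10)
})

test_that("reliability slope stays near one under 1% noise", {
  m <- aggregation_model(3, 1.4e9, 0.241, 0.027, 1)
  C <- exp(seq(log(0.518e-6), log(133e-6), length.out = 24))
  A0 <- predict_integral_absorbance(m, C)
  set.seed(5)
  cv <- absorbance_curve(C, A0 * (1 + rnorm(24, 0, 0.01)))
  fit <- fit_aggregation(cv)
  expect_gte(fit$reliability$slope_calc_vs_exp, 0.95)
  expect_lte(fit$reliability$slope_calc_vs_exp, 1.05)
})

test_that("bootstrap intervals are deterministic and collapse without noise", {
  m <- aggregation_model(3, 1.4e9, 0.241, 0.027, 1)
  C <- exp(seq(log(0.518e-6), log(133e-6), length.out = 24))
  cv <- model_curve(m, C)
  ex <- suppressMessages(excess_absorbance(cv, 0.241))

  ci1 <- bootstrap_K(ex, 3, n_boot = 100, seed = 9)
  ci2 <- bootstrap_K(ex, 3, n_boot = 100, seed = 9)
  expect_identical(ci1, ci2)
  # noiseless data: the interval degenerates onto the true K
  expect_lt((ci1[["hi"]] - ci1[["lo"]]) / 1.4e9, 1e-6)
  expect_equal(mean(c(ci1[["lo"]], ci1[["hi"]])), 1.4e9, tolerance = 1e-3)

  expect_error(bootstrap_K(ex, 3, n_boot = 10), ">= 50")
})

test_that("bootstrap interval covers the generating K under noise", {
  m <- aggregation_model(3, 1.4e9, 0.241, 0.027, 1)
  C <- exp(seq(log(0.518e-6), log(133e-6), length.out = 24))
  A0 <- predict_integral_absorbance(m, C)
  cover <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    cv <- absorbance_curve(C, A0 * (1 + rnorm(24, 0, 0.01)))
    ex <- suppressMessages(excess_absorbance(cv, 0.241))
    ci <- bootstrap_K(ex, 3, n_boot = 200, seed = s)
    if (ci[["lo"]] <= 1.4e9 && 1.4e9 <= ci[["hi"]]) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("the pipeline aborts with the failing stage's name", {
  expect_error(fit_aggregation(absorbance_curve(1:2, c(1, 2))),
               "stage 'limiting slope'")
  # pure Lambert-Beer data: no excess signal anywhere in the scan
  lb <- absorbance_curve(1:6 * 1e-6, 1:6 * 1e-6 * 2)
  expect_error(fit_aggregation(lb, refine_slope = FALSE), "stage")
})

test_that("noiseless pipeline recovers arbitrary random models to 0.1%", {
  set.seed(51)
  for (i in 1:6) {
    case <- random_model_case()
    cv <- model_curve(case$model, case$C)
    fit <- fit_aggregation(cv)
    expect_equal(fit$model$n, case$model$n)
    expect_equal(fit$model$K_n, case$model$K_n, tolerance = 1e-3)
    expect_equal(attr(fit$model, "delta_n"),
                 abs(case$model$eps1 - case$model$epsn) * case$model$path_length,
                 tolerance = 1e-3)
  }
})
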