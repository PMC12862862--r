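test_that("correlation matches hand-computed values and handles edge cases", {
  expect_equal(correlate(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  # hand evaluation of the product-moment sums
  expect_equal(correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  x <- c(1, 2, 3, 4, 5)
  y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$r, 1.0)
  expect_lt(correlate(x, y, "pearson")$r, 1.0)
  expect_warning(r0 <- correlate(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r0$r))
  expect_error(correlate(1:2, 2:3), "3")
})

test_that("pearson correlation is invariant to positive affine transforms", {
  set.seed(1)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r0 <- correlate(x, y)$r
  expect_equal(correlate(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(correlate(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
})

test_that("lag scan recovers a constructed shift exactly and nulls stay flat", {
  panel <- shifted_pair_panel(lag = 3)
  scan <- lag_correlation_scan(panel, "a", "b", max_lag = 5, n_boot = 20)
  expect_equal(scan$peak_lag, 3)
  expect_gt(scan$peak_r, 0.999)

  set.seed(2)
  null_rows <- lapply(1:200, function(i) tibble::tibble(
    athlete_id = sprintf("N%03d", i), group = "g",
    time_index = rep(0:23, 2), feature = rep(c("a", "b"), each = 24),
    value = rnorm(48)))
  null_panel <- dplyr::bind_rows(null_rows)
  null_scan <- lag_correlation_scan(null_panel, "a", "b", max_lag = 4,
                                    n_boot = 20)
  expect_lt(abs(null_scan$peak_r), 0.1)
})

test_that("lag-0 scan equals the pooled within-athlete correlation", {
  panel <- small_panel()
  scan <- lag_correlation_scan(panel, "fatigue", "stress", max_lag = 2,
                               n_boot = 10)
  w <- panel_wide(panel)
  per <- sapply(split(w, w$athlete_id), function(d)
    cor(d$fatigue[order(d$time_index)], d$stress[order(d$time_index)]))
  pooled <- tanh(mean(atanh(pmin(pmax(per, -0.999999), 0.999999))))
  expect_equal(scan$scan$r[scan$scan$lag == 0], pooled, tolerance = 1e-10)
})

test_that("first canonical correlation behaves on known block structures", {
  set.seed(3)
  x <- matrix(rnorm(200 * 4), 200)
  expect_equal(first_canonical_correlation(x, x)$r1, 1, tolerance = 1e-8)
  a <- rnorm(100); b <- 0.6 * a + rnorm(100)
  expect_equal(first_canonical_correlation(matrix(a), matrix(b))$r1,
               abs(cor(a, b)), tolerance = 1e-10)
  y <- matrix(rnorm(200 * 4), 200)
  r_obs <- first_canonical_correlation(x, y)$r1
  null_r <- replicate(60, first_canonical_correlation(
    x[sample(200), ], y)$r1)
  expect_lt(r_obs, quantile(null_r, 0.95) + 0.05)
  # rank-deficient blocks still produce a finite leading correlation
  xs <- cbind(x[, 1], x[, 1], x[, 2])
  rs <- suppressWarnings(first_canonical_correlation(xs, y))
  expect_true(is.finite(rs$r1))
  expect_gte(rs$r1, 0); expect_lte(rs$r1, 1)
})

test_that("serial mediation: null b-paths, seeding, and collinearity guard", {
  d0 <- simulate_mediation_data(300, a1 = 0.5, a2 = 0.6, b1 = 0, b2 = 0,
                                cprime = 0.3, seed = 2)
  m0 <- fit_mediation_serial(d0, n_boot = 400, seed = 1)
  ser <- m0$paths[m0$paths$term == "indirect_serial", ]
  expect_true(ser$ci_lo <= 0 && 0 <= ser$ci_hi)
  sim <- m0$paths[m0$paths$term == "indirect_simple", ]
  expect_true(sim$ci_lo <= 0 && 0 <= sim$ci_hi)

  m0b <- fit_mediation_serial(d0, n_boot = 400, seed = 1)
  expect_identical(m0$paths$ci_lo, m0b$paths$ci_lo)

  dc <- d0; dc$m2 <- dc$m1
  expect_error(fit_mediation_serial(dc, n_boot = 10), "collinear")
  expect_error(fit_mediation_serial(d0[1:20, ], n_boot = 10), "n >= 30")
})

test_that("the OLS effect decomposition is an algebraic identity", {
  d <- simulate_mediation_data(200, noise_sd = 1, seed = 9)
  p <- pniflow:::mediation_paths(d, "x", c("m1", "m2"), "y")
  expect_equal(unname(p["total"]),
               unname(p["cprime"] + p["indirect_simple"] +
                        p["indirect_serial"] + p["indirect_xm2"]),
               tolerance = 1e-10)
})

test_that("bootstrap CI coverage of the serial indirect effect is near 95%", {
  true_val <- 0.5 * 0.6 * 0.4
  hits <- 0
  reps <- 120
  for (r in seq_len(reps)) {
    d <- simulate_mediation_data(150, seed = 1000 + r)
    m <- fit_mediation_serial(d, n_boot = 300, seed = r)
    ser <- m$paths[m$paths$term == "indirect_serial", ]
    hits <- hits + (ser$ci_lo <= true_val && true_val <= ser$ci_hi)
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
})

test_that("proportion mediated reproduces reported-table arithmetic", {
  expect_equal(round(proportion_mediated(indirect = c(0.22, 0.35),
                                         total = 0.81), 1), 70.4)
  expect_equal(round(proportion_mediated(indirect = c(0.15, 0.12),
                                         total = 0.58), 1), 46.6)
  expect_equal(proportion_mediated(indirect = c(0, 0), total = 0.5), 0)
  expect_warning(pm <- proportion_mediated(indirect = 0.1, total = 0),
                 "zero")
  expect_true(is.na(pm))
})

test_that("ARIMA order selection recovers simulated processes", {
  set.seed(4)
  ar1 <- arima.sim(list(ar = 0.8), 500)
  f_ar <- fit_arima(ar1)
  expect_equal(unname(f_ar$order), c(1, 0, 0))
  expect_gt(f_ar$coefficients[["ar1"]], 0.7)
  expect_lt(f_ar$coefficients[["ar1"]], 0.9)
  # parsimony tie-break keeps the fit within the 2-point AIC band
  expect_lte(f_ar$aic, min(f_ar$candidates$aic, na.rm = TRUE) + 2)

  wn <- rnorm(400)
  expect_equal(unname(fit_arima(wn)$order), c(0, 0, 0))

  rw <- cumsum(rnorm(400))
  expect_equal(unname(fit_arima(rw)$order[2]), 1)

  expect_error(fit_arima(rnorm(10)), ">= 30")
})

test_that("threshold crossing lag interpolates first crossings", {
  months <- 0:12
  a <- pmin(months / 8, 1)            # crosses 0.5 at month 4
  b <- pmin(months / 11, 1)           # crosses 0.5 at month 5.5
  expect_equal(threshold_crossing_lag(months, a, b, 0.5), 1.5)
  expect_equal(threshold_crossing_lag(months, a, a, 0.5), 0)
  expect_true(is.na(threshold_crossing_lag(months, a, rep(0.1, 13), 0.5)))
})

test_that("the generator's psychological lead shows up as a crossing lag", {
  panel <- small_panel()
  w <- panel_wide(panel)
  tt <- max(w$time_index) + 1
  mean_traj <- function(f, flip) {
    v <- tapply(w[[f]], w$time_index, mean)
    v <- if (flip) v[1] - v else v - v[1]
    v / v[length(v)]
  }
  months <- steps_to_months(0:(tt - 1), tt)
  lag_m <- threshold_crossing_lag(months, mean_traj("fatigue", TRUE),
                                  mean_traj("il6", TRUE), 0.5)
  expect_gte(lag_m, 0.8)
  expect_lte(lag_m, 2.5)
})
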