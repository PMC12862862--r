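#' Pearson or Spearman correlation with a p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3 finite pairs).
#' @param method `"pearson"` or `"spearman"` (rank transform then Pearson).
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlate: need at least 3 finite pairs",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlate: zero variance input; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                method = method))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Lagged cross-correlation scan between two feature trajectories
#'
#' For each lag `l` in `-max_lag .. max_lag`, correlates athlete `a(t)` with
#' `b(t + l)` within athlete, pools the per-athlete correlations by
#' Fisher-z averaging, and bootstraps a confidence interval over athletes.
#' A positive peak lag means `series_a` leads `series_b`.
#'
#' @param panel Long-format panel.
#' @param series_a,series_b Feature names.
#' @param max_lag Maximum lag in bi-weekly steps (must be < T/2).
#' @param n_boot Bootstrap draws over athletes for the CI (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return List of class `lag_scan`: tibble `scan` (lag, months, r, ci_lo,
#'   ci_hi, n_athletes), `peak_lag`, `peak_months`, `peak_r`.
#' @export
lag_correlation_scan <- function(panel, series_a, series_b, max_lag = 6,
                                 n_boot = 200, conf = 0.95, seed = 1L) {
  check_panel(panel)
  wide <- panel_wide(dplyr::filter(panel,
                                   .data$feature %in% c(series_a, series_b)))
  tt <- max(wide$time_index) + 1
  if (max_lag >= tt / 2) {
    stop("lag_correlation_scan: max_lag must be below T/2", call. = FALSE)
  }
  split_w <- split(wide, wide$athlete_id)
  lags <- -max_lag:max_lag
  per_athlete <- matrix(NA_real_, length(split_w), length(lags),
                        dimnames = list(names(split_w), lags))
  for (i in seq_along(split_w)) {
    d <- split_w[[i]][order(split_w[[i]]$time_index), ]
    a <- d[[series_a]]; b <- d[[series_b]]
    for (k in seq_along(lags)) {
      l <- lags[k]
      if (l >= 0) { av <- a[seq_len(tt - l)]; bv <- b[seq_len(tt - l) + l] }
      else { av <- a[seq_len(tt + l) - l]; bv <- b[seq_len(tt + l)] }
      ok <- is.finite(av) & is.finite(bv)
      if (sum(ok) >= 3 && stats::sd(av[ok]) > 0 && stats::sd(bv[ok]) > 0) {
        per_athlete[i, k] <- stats::cor(av[ok], bv[ok])
      }
    }
  }
  fisher_pool <- function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) return(NA_real_)
    tanh(mean(atanh(pmin(pmax(r, -0.999999), 0.999999))))
  }
  r_pooled <- apply(per_athlete, 2, fisher_pool)
  skipped <- lags[is.na(r_pooled)]
  if (length(skipped)) {
    warning("lag_correlation_scan: insufficient overlap at lag(s) ",
            paste(skipped, collapse = ", "), "; skipped")
  }
  set.seed(seed)
  na <- nrow(per_athlete)
  boot <- matrix(NA_real_, n_boot, length(lags))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(na, na, replace = TRUE)
    boot[b, ] <- apply(per_athlete[idx, , drop = FALSE], 2, fisher_pool)
  }
  alpha <- (1 - conf) / 2
  scan <- tibble::tibble(
    lag = lags,
    months = steps_to_months(lags, tt),
    r = unname(r_pooled),
    ci_lo = apply(boot, 2, stats::quantile, alpha, na.rm = TRUE),
    ci_hi = apply(boot, 2, stats::quantile, 1 - alpha, na.rm = TRUE),
    n_athletes = colSums(is.finite(per_athlete)))
  peak_idx <- which.max(scan$r)
  structure(list(scan = scan, peak_lag = scan$lag[peak_idx],
                 peak_months = scan$months[peak_idx],
                 peak_r = scan$r[peak_idx],
                 series_a = series_a, series_b = series_b),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("<lag_scan> %s leads %s: peak r = %.3f at lag %d steps (%.1f months)\n",
              x$series_a, x$series_b, x$peak_r, x$peak_lag, x$peak_months))
  invisible(x)
}

#' First canonical correlation between two variable blocks
#'
#' Leading canonical correlation via the standard generalised-eigenvalue
#' formulation (`stats::cancor` on centred blocks); singular within-block
#' covariance triggers a ridge-regularised eigendecomposition with a
#' warning.
#'
#' @param block_x,block_y Numeric matrices / data frames, n rows each.
#' @return List with `r1` and `shared_variance_pct` (= 100 * r1^2).
#' @export
first_canonical_correlation <- function(block_x, block_y) {
  x <- scale(as.matrix(block_x), scale = FALSE)
  y <- scale(as.matrix(block_y), scale = FALSE)
  if (nrow(x) <= ncol(x) + ncol(y)) {
    stop("first_canonical_correlation: need n > total dimensions",
         call. = FALSE)
  }
  r1 <- tryCatch(stats::cancor(x, y)$cor[1], error = function(e) NA_real_)
  if (is.na(r1)) {
    warning("first_canonical_correlation: singular within-block covariance; ",
            "applying ridge regularisation")
    sxx <- stats::cov(x); syy <- stats::cov(y); sxy <- stats::cov(x, y)
    eps_x <- 1e-6 * mean(diag(sxx)); eps_y <- 1e-6 * mean(diag(syy))
    m <- solve(sxx + eps_x * diag(ncol(x)), sxy) %*%
      solve(syy + eps_y * diag(ncol(y)), t(sxy))
    r1 <- sqrt(max(Re(eigen(m, only.values = TRUE)$values)))
  }
  list(r1 = unname(r1), shared_variance_pct = 100 * r1^2)
}

#' Serial mediation analysis with bootstrap confidence intervals
#'
#' Ordinary-least-squares path regressions for the chain
#' exposure -> mediator 1 -> mediator 2 -> outcome:
#' `m1 ~ x` (a1), `m2 ~ m1 + x` (a2, a3), `y ~ x + m1 + m2` (c', b1, b2),
#' `y ~ x` (total c). Indirect effects are coefficient products
#' (`a1*b1`, `a1*a2*b2`, and `a3*b2`); their bias-corrected percentile
#' bootstrap CIs use `n_boot` resamples. On linear-Gaussian data the OLS
#' decomposition `c = c' + a1 b1 + a1 a2 b2 + a3 b2` is an algebraic
#' identity.
#'
#' @param data Data frame with the model columns.
#' @param exposure,mediators,outcome Column names; `mediators` is
#'   `c(m1, m2)` for the serial model or a single name for simple
#'   mediation.
#' @param n_boot Bootstrap iterations (default 5000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return Object of class `mediation_result`.
#' @export
fit_mediation_serial <- function(data, exposure = "x",
                                 mediators = c("m1", "m2"), outcome = "y",
                                 n_boot = 5000, conf = 0.95, seed = 1L) {
  data <- as.data.frame(data)[, c(exposure, mediators, outcome)]
  data <- data[stats::complete.cases(data), ]
  n <- nrow(data)
  if (n < 30) stop("fit_mediation_serial: need n >= 30", call. = FALSE)
  serial <- length(mediators) == 2
  mm <- as.matrix(data[, c(exposure, mediators)])
  if (serial) {
    kappa_val <- kappa(cbind(1, mm), exact = TRUE)
    if (kappa_val > 1e6) {
      stop("fit_mediation_serial: collinear mediators (condition number ",
           format(kappa_val, digits = 3), ")", call. = FALSE)
    }
  }
  est <- function(d) mediation_paths(d, exposure, mediators, outcome)
  point <- est(data)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- est(data[sample.int(n, n, replace = TRUE), ])
  }
  ci <- t(vapply(names(point), function(nm) {
    bc_ci(boot[, nm], point[[nm]], conf)
  }, numeric(2)))
  colnames(ci) <- c("ci_lo", "ci_hi")
  se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  indirect_names <- if (serial) {
    c("indirect_simple", "indirect_serial", "indirect_xm2")
  } else "indirect_simple"
  prop <- 100 * sum(point[indirect_names]) / point[["total"]]
  structure(list(
    paths = tibble::tibble(term = names(point), estimate = unname(point),
                           se = unname(se), ci_lo = ci[, 1], ci_hi = ci[, 2]),
    indirect_simple = point[["indirect_simple"]],
    indirect_serial = if (serial) point[["indirect_serial"]] else NA_real_,
    total = point[["total"]], direct = point[["cprime"]],
    proportion_mediated = prop,
    n = n, n_boot = n_boot, conf = conf, serial = serial),
    class = "mediation_result")
}

mediation_paths <- function(d, exposure, mediators, outcome) {
  x <- d[[exposure]]; y <- d[[outcome]]
  one <- rep(1, length(x))
  cf <- function(X, yy) stats::lm.fit(X, yy)$coefficients
  if (length(mediators) == 2) {
    m1 <- d[[mediators[1]]]; m2 <- d[[mediators[2]]]
    a1 <- cf(cbind(one, x), m1)[2]
    f2 <- cf(cbind(one, m1, x), m2); a2 <- f2[2]; a3 <- f2[3]
    fy <- cf(cbind(one, x, m1, m2), y)
    cprime <- fy[2]; b1 <- fy[3]; b2 <- fy[4]
    total <- cf(cbind(one, x), y)[2]
    c(a1 = unname(a1), a2 = unname(a2), a3 = unname(a3), b1 = unname(b1),
      b2 = unname(b2), cprime = unname(cprime), total = unname(total),
      indirect_simple = unname(a1 * b1),
      indirect_serial = unname(a1 * a2 * b2),
      indirect_xm2 = unname(a3 * b2))
  } else {
    m1 <- d[[mediators[1]]]
    a1 <- cf(cbind(one, x), m1)[2]
    fy <- cf(cbind(one, x, m1), y)
    cprime <- fy[2]; b1 <- fy[3]
    total <- cf(cbind(one, x), y)[2]
    c(a1 = unname(a1), b1 = unname(b1), cprime = unname(cprime),
      total = unname(total), indirect_simple = unname(a1 * b1))
  }
}

# Bias-corrected percentile bootstrap interval.
bc_ci <- function(boot, point, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (!length(boot)) return(c(NA_real_, NA_real_))
  prop_below <- mean(boot < point)
  prop_below <- min(max(prop_below, 1 / length(boot)),
                    1 - 1 / length(boot))
  z0 <- stats::qnorm(prop_below)
  alpha <- (1 - conf) / 2
  lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  unname(stats::quantile(boot, c(lo_p, hi_p)))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>", if (x$serial) "serial (x -> m1 -> m2 -> y)"
      else "simple (x -> m1 -> y)", "\n")
  print(x$paths, n = nrow(x$paths))
  cat(sprintf("proportion mediated: %.1f%%  (n = %d, %d bootstrap draws)\n",
              x$proportion_mediated, x$n, x$n_boot))
  invisible(x)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * sum(indirect effects) / total effect`. Accepts either a fitted
#' [fit_mediation_serial()] result or explicit numeric values (as reported
#' in a mediation table).
#'
#' @param result A `mediation_result`, or `NULL` when using `indirect` /
#'   `total` directly.
#' @param indirect Numeric vector of indirect effects.
#' @param total Total effect (must be nonzero).
#' @param tol Magnitude below which the total effect is treated as zero.
#' @return Percentage (possibly `NA` with a warning).
#' @export
proportion_mediated <- function(result = NULL, indirect = NULL, total = NULL,
                                tol = 1e-8) {
  if (!is.null(result)) {
    stopifnot(inherits(result, "mediation_result"))
    return(result$proportion_mediated)
  }
  if (abs(total) < tol) {
    warning("proportion_mediated: total effect is zero; proportion undefined")
    return(NA_real_)
  }
  100 * sum(indirect) / total
}

#' ARIMA fit with AIC order selection
#'
#' Fits `arima(p, d, q)` by maximum likelihood over an order grid and keeps
#' the AIC-minimising order; candidates within `aic_margin` of the minimum
#' are treated as tied and resolved toward fewer parameters (plain AIC
#' argmin is known to overfit the order, so models whose fit is not
#' substantially better than a simpler one do not displace it). Ties break
#' toward fewer parameters, then lower differencing. Non-convergent orders
#' are skipped with a warning.
#'
#' @param series Numeric series (length >= 30).
#' @param order_grid Data frame with columns `p`, `d`, `q` (default: all
#'   `p, q <= 2`, `d <= 1`).
#' @param aic_margin AIC band counted as a tie (default 4, roughly a
#'   nested likelihood-ratio test at the 1-2% level per extra parameter).
#' @return List of class `arima_fit`: `order`, `coefficients`, `aic`,
#'   `residuals`, `model`, and the full `candidates` table.
#' @export
fit_arima <- function(series,
                      order_grid = expand.grid(p = 0:2, d = 0:1, q = 0:2),
                      aic_margin = 4) {
  series <- as.numeric(series)
  if (length(series) < 30) stop("fit_arima: series length must be >= 30",
                                call. = FALSE)
  fits <- vector("list", nrow(order_grid))
  aics <- rep(NA_real_, nrow(order_grid))
  for (i in seq_len(nrow(order_grid))) {
    ord <- unlist(order_grid[i, c("p", "d", "q")])
    fits[i] <- list(tryCatch(
      stats::arima(series, order = ord, include.mean = ord[2] == 0,
                   method = "ML"),
      error = function(e) NULL, warning = function(w) NULL))
    if (!is.null(fits[[i]])) aics[i] <- fits[[i]]$aic
  }
  if (all(is.na(aics))) stop("fit_arima: no candidate order converged",
                             call. = FALSE)
  if (any(is.na(aics))) {
    bad <- order_grid[is.na(aics), , drop = FALSE]
    warning("fit_arima: skipped non-convergent order(s) ",
            paste(sprintf("(%d,%d,%d)", bad$p, bad$d, bad$q), collapse = " "))
  }
  n_par <- order_grid$p + order_grid$q
  tied <- which(aics <= min(aics, na.rm = TRUE) + aic_margin)
  pick <- tied[order(n_par[tied], order_grid$d[tied], aics[tied])[1]]
  best <- fits[[pick]]
  structure(list(
    order = unlist(order_grid[pick, c("p", "d", "q")]),
    coefficients = stats::coef(best), aic = best$aic,
    residuals = as.numeric(stats::residuals(best)), model = best,
    candidates = tibble::tibble(p = order_grid$p, d = order_grid$d,
                                q = order_grid$q, aic = aics)),
    class = "arima_fit")
}

#' @export
print.arima_fit <- function(x, ...) {
  cat(sprintf("<arima_fit> order (%d,%d,%d), AIC = %.2f\n",
              x$order[1], x$order[2], x$order[3], x$aic))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Lag between two trajectories reaching an improvement threshold
#'
#' Linear-interpolated first crossing time of each normalised trajectory;
#' returns `crossing(b) - crossing(a)` in months (positive when trajectory
#' `a` reaches the threshold first).
#'
#' @param months Shared time grid (months, increasing).
#' @param traj_a,traj_b Normalised improvement trajectories (increasing
#'   toward 1).
#' @param threshold Crossing threshold.
#' @return Lag in months, or `NA` when either trajectory never crosses.
#' @export
threshold_crossing_lag <- function(months, traj_a, traj_b, threshold = 0.5) {
  stopifnot(length(months) == length(traj_a),
            length(months) == length(traj_b))
  cross <- function(v) {
    above <- which(v >= threshold)
    if (!length(above)) return(NA_real_)
    j <- above[1]
    if (j == 1) return(months[1])
    months[j - 1] + (threshold - v[j - 1]) / (v[j] - v[j - 1]) *
      (months[j] - months[j - 1])
  }
  ca <- cross(traj_a); cb <- cross(traj_b)
  if (is.na(ca) || is.na(cb)) return(NA_real_)
  cb - ca
}
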