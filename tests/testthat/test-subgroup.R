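test_that("tertile stratification sizes and determinism", {
  nine <- tibble::tibble(athlete_id = letters[1:9], value = c(9:1))
  labs <- stratify_tertiles(nine)
  expect_equal(unname(table(labs)[c("low", "moderate", "high")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(unname(labs[c("i", "e", "a")]), c("low", "moderate", "high"))

  big <- tibble::tibble(athlete_id = sprintf("A%03d", 1:200),
                        value = rnorm(200))
  sizes <- table(stratify_tertiles(big))
  expect_equal(unname(sizes[c("low", "moderate", "high")]), c(67L, 66L, 67L),
               ignore_attr = TRUE)

  tied <- tibble::tibble(athlete_id = letters[1:6], value = rep(1, 6))
  expect_warning(labs2 <- stratify_tertiles(tied), "tied")
  expect_equal(unname(labs2), rep(c("low", "moderate", "high"), each = 2))
  expect_error(stratify_tertiles(tied[1:2, ]), "3")
})

test_that("random-intercept model recovers planted parameters", {
  set.seed(5)
  n <- 150; t_per <- 8
  u <- rnorm(n, 0, 1)
  d <- tidyr::expand_grid(i = seq_len(n), t = seq_len(t_per))
  d$x <- rnorm(nrow(d))
  d$y <- 1 + 2 * d$x + u[d$i] + rnorm(nrow(d), 0, 1)
  panel <- tibble::tibble(
    athlete_id = rep(sprintf("A%03d", d$i), 2), group = "g",
    time_index = rep(d$t - 1L, 2),
    feature = rep(c("y", "x"), each = nrow(d)),
    value = c(d$y, d$x))
  fit <- fit_random_intercept(panel, "y", "x")
  b1 <- fit$fixed$estimate[fit$fixed$term == "x"]
  expect_gt(b1, 1.8); expect_lt(b1, 2.2)
  expect_lt(abs(fit$random_intercept_var - 1), 0.35)
  expect_lt(abs(fit$residual_var - 1), 0.25)
})

test_that("zero random-intercept variance reduces to ordinary regression", {
  set.seed(6)
  n <- 200; t_per <- 10
  d <- tidyr::expand_grid(i = seq_len(n), t = seq_len(t_per))
  d$x <- rnorm(nrow(d))
  d$y <- 0.5 + 1.5 * d$x + rnorm(nrow(d))
  panel <- tibble::tibble(
    athlete_id = rep(sprintf("A%03d", d$i), 2), group = "g",
    time_index = rep(d$t - 1L, 2),
    feature = rep(c("y", "x"), each = nrow(d)), value = c(d$y, d$x))
  fit <- suppressMessages(fit_random_intercept(panel, "y", "x"))
  ols <- lm(y ~ x, data = d)
  expect_lt(abs(fit$fixed$estimate[fit$fixed$term == "x"] -
                  coef(ols)[["x"]]), 1e-3)
})

test_that("change summaries reproduce reported arithmetic exactly", {
  groups <- c("high_carb", "high_protein", "balanced")
  fat <- exact_change_panel(groups, c(5.8, 5.2, 4.6), c(1.0, 1.0, 1.0),
                            c(5.0, 4.0, 2.8), c(0.9, 0.9, 0.8))
  s <- summarize_change(fat, "fatigue")
  expect_equal(s$delta[match(groups, s$group)], c(-0.8, -1.2, -1.8))
  res <- exact_change_panel(groups, c(4.8, 5.4, 6.0), c(0.9, 0.9, 0.9),
                            c(5.5, 6.5, 7.5), c(0.9, 0.8, 0.8),
                            outcome = "resilience")
  sr <- summarize_change(res, "resilience")
  expect_equal(round(sr$percent_change[match(groups, sr$group)], 1),
               c(14.6, 20.4, 25.0))
})

test_that("MCID boundary counts as improved and the rule uses max(1, 0.5 SD)", {
  n <- 20
  panel <- tibble::tibble(
    athlete_id = rep(sprintf("A%02d", 1:n), each = 2), group = "balanced",
    time_index = rep(c(0L, 23L), n), feature = "fatigue",
    value = as.numeric(rbind(rnorm(n, 6, 0.5), NA)))
  panel$value[panel$time_index == 23] <-
    panel$value[panel$time_index == 0] - 1.0    # exactly the MCID
  s <- summarize_change(panel, "fatigue")
  expect_equal(s$clinical_improvement_pct, 100)
  expect_equal(s$mcid, 1.0)
})

test_that("within-group test falls back to Wilcoxon for skewed changes", {
  set.seed(8)
  n <- 60
  base <- rnorm(n, 6, 0.3)
  end <- base - exp(rnorm(n, 0, 1))   # heavily skewed improvements
  panel <- tibble::tibble(
    athlete_id = rep(sprintf("A%02d", 1:n), each = 2), group = "g",
    time_index = rep(c(0L, 23L), n), feature = "fatigue",
    value = as.numeric(rbind(base, end)))
  s <- summarize_change(panel, "fatigue")
  expect_lt(s$p_value, 0.01)
})

test_that("response characterisation finds onset, rate and plateau", {
  flat <- characterize_response(0:12, rep(5, 13), mcid = 0.5)
  expect_true(is.na(flat$onset_months))
  expect_equal(flat$improvement_rate, 0)

  months <- 0:12
  lin <- 6 - 0.2 * months           # steady 0.2 points/month decline
  r <- characterize_response(months, lin, mcid = 0.2, plateau_slope = 0.01)
  expect_equal(r$improvement_rate, 0.2, tolerance = 0.01)

  # saturating trajectory with known dynamics: onset 1.2, plateau 6.8
  frac <- pniflow:::saturating_fraction(months, 1.2, 6.8)
  sat <- 5.4 - 2.6 * frac
  rs <- characterize_response(months, sat, mcid = 0.4)
  expect_gte(rs$plateau_months, 5.8)
  expect_lte(rs$plateau_months, 7.8)
  expect_lt(rs$onset_months, 3)
})

test_that("tertile response ordering matches the planted dynamics", {
  ok_onset <- 0
  for (s in 1:3) {
    panel <- generate_cohort(small_spec(seed = 30 + s))
    prof <- subgroup_profiles(panel)
    o <- prof$onset_months[match(c("high", "moderate", "low"), prof$tertile)]
    if (!anyNA(o) && o[1] < o[2] && o[2] < o[3]) ok_onset <- ok_onset + 1
  }
  expect_gte(ok_onset, 2)

  # plateau ordering needs full-cohort group means (the slope margin
  # between tertiles is ~1.5 months)
  prof <- subgroup_profiles(full_panel())
  p <- prof$plateau_months[match(c("high", "moderate", "low"),
                                 prof$tertile)]
  p[is.na(p)] <- Inf   # no plateau inside the window = right-censored late
  expect_lt(p[1], p[3])
  o <- prof$onset_months[match(c("high", "moderate", "low"), prof$tertile)]
  expect_true(o[1] < o[2] && o[2] < o[3])
})

test_that("Bonferroni adjustment multiplies by family size with capping", {
  expect_equal(adjust_pvalues(0.01, family = rep(1, 1)), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.2, 0.3, 0.4))[1], 0.04)
  expect_equal(adjust_pvalues(c(0.4, 0.5, 0.6, 0.7))[1], 1.0)
  mixed <- adjust_pvalues(c(0.01, 0.01, 0.01), family = c("a", "a", "b"))
  expect_equal(mixed, c(0.02, 0.02, 0.01))
})
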