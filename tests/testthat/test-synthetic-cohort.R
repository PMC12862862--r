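test_that("group sizes are exact and seeded generation is reproducible", {
  spec <- cohort_spec(seed = 5)
  base <- generate_baseline(spec)
  sizes <- table(panel_athletes(base)$group)
  expect_equal(unname(sizes[c("high_carb", "high_protein", "balanced")]),
               c(68, 65, 67), ignore_attr = TRUE)
  expect_equal(sum(sizes), 200)

  p1 <- generate_cohort(small_spec(seed = 3))
  p2 <- generate_cohort(small_spec(seed = 3))
  expect_identical(p1, p2)
  p3 <- generate_cohort(small_spec(seed = 4))
  expect_false(identical(p1$value, p3$value))
})

test_that("panels written to CSV are byte-identical across runs", {
  panel <- generate_baseline(small_spec(seed = 8))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_panel(panel, f1)
  write_panel(panel, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_panel(f1)
  expect_equal(nrow(back), nrow(panel))
  expect_equal(back$value, panel$value, tolerance = 1e-9)
})

test_that("degenerate variance collapses values onto the group mean", {
  prof <- default_baseline_profiles()
  for (f in names(prof)) prof[[f]]$sd[] <- 1e-9
  spec <- cohort_spec(baseline_profiles = prof, seed = 2)
  base <- generate_baseline(spec)
  fat <- dplyr::filter(base, feature == "fatigue", group == "balanced")
  expect_true(all(abs(fat$value - 4.6) < 1e-6))
})

test_that("baseline means reproduce the calibration within 3 standard errors", {
  checks <- list(fatigue = c(high_carb = 5.8, balanced = 4.6),
                 il6 = c(high_carb = 3.24, balanced = 2.31),
                 iga = c(high_carb = 176.3, balanced = 198.5),
                 cortisol = c(high_protein = 441.2, balanced = 436.8))
  # average over seeds against the single-cohort standard error
  seeds <- 1:5
  base_means <- lapply(seeds, function(s) {
    b <- panel_wide(generate_baseline(cohort_spec(seed = s)))
    sapply(names(checks), function(f) tapply(b[[f]], b$group, mean))
  })
  prof <- default_baseline_profiles()
  for (f in names(checks)) {
    for (g in names(checks[[f]])) {
      mu <- mean(sapply(base_means, function(m) m[g, f]))
      n_g <- c(high_carb = 68, high_protein = 65, balanced = 67)[[g]]
      se <- prof[[f]]$sd[[g]] / sqrt(n_g)
      expect_lt(abs(mu - checks[[f]][[g]]), 3 * se,
                label = sprintf("|mean-target| for %s/%s", f, g))
    }
  }
})

test_that("trajectory endpoints hit their targets and zero rate means no change", {
  w <- panel_wide(full_panel())
  tmax <- max(w$time_index)
  endf <- w[w$time_index == tmax, ]
  expect_lt(abs(mean(endf$fatigue[endf$group == "balanced"]) - 2.8),
            3 * 0.8 / sqrt(67))
  expect_lt(abs(mean(endf$cortisol[endf$group == "high_carb"]) - 398.7),
            3 * 71.4 / sqrt(68))

  dyn <- default_subgroup_dynamics()
  for (tr in names(dyn)) dyn[[tr]]$rate_per_month <- 0
  spec0 <- cohort_spec(n_per_group = c(high_carb = 20, high_protein = 20,
                                       balanced = 20),
                       subgroup_dynamics = dyn, seed = 6)
  p0 <- generate_cohort(spec0)
  w0 <- panel_wide(p0)
  for (g in unique(w0$group)) {
    b <- mean(w0$fatigue[w0$time_index == 0 & w0$group == g])
    e <- mean(w0$fatigue[w0$time_index == max(w0$time_index) & w0$group == g])
    expect_lt(abs(e - b), 3 * 1.0 / sqrt(20) + 0.2)
  }
})

test_that("generated intake columns reproduce the dietary-pattern labels", {
  b <- panel_wide(generate_baseline(small_spec(seed = 11)))
  expect_identical(classify_dietary_pattern(b$carb_pct_energy,
                                            b$protein_g_kg), b$group)
})

test_that("the noiseless mediation chain recovers a1*a2*b2 to 3 decimals", {
  # noiseless limit = large n with moderate structural noise: vanishing
  # noise makes x and m1 collinear and the path regressions ill-conditioned
  d <- simulate_mediation_data(50000, a1 = 0.5, a2 = 0.6, b1 = 0.4, b2 = 0.4,
                               cprime = 0.2, noise_sd = 0.2, seed = 1)
  paths <- pniflow:::mediation_paths(d, "x", c("m1", "m2"), "y")
  expect_equal(unname(paths["indirect_serial"]), 0.5 * 0.6 * 0.4,
               tolerance = 1e-3)
  expect_equal(unname(paths["total"]),
               0.2 + 0.5 * 0.4 + 0.5 * 0.6 * 0.4, tolerance = 5e-3)
})

test_that("the lag-correlation peak recovers the planted lag", {
  hits <- 0
  for (s in 1:3) {
    panel <- generate_cohort(small_spec(seed = s + 20))
    scan <- lag_correlation_scan(panel, "fatigue", "il6", max_lag = 6,
                                 n_boot = 20, seed = s)
    hits <- hits + (abs(scan$peak_lag - 3) <= 1)
  }
  expect_gte(hits, 2)
})

test_that("degradation masks the requested fraction and respects identity", {
  panel <- small_panel()
  spec0 <- small_spec(); spec0$missing_rate <- 0; spec0$outlier_rate <- 0
  same <- degrade_panel(panel, spec0)
  expect_equal(same$value, panel$value)

  spec1 <- small_spec(); spec1$missing_rate <- 0.1
  degraded <- degrade_panel(panel, spec1)
  frac <- degraded |>
    dplyr::group_by(athlete_id) |>
    dplyr::summarise(f = mean(is.na(value)))
  expect_true(all(abs(frac$f - 0.1) < 0.02))   # direct count oracle
  expect_true(all(frac$f < 0.2))
  gt <- attr(degraded, "ground_truth")
  expect_equal(sum(is.na(degraded$value)), sum(gt$kind == "missing"))
})

test_that("injected outliers are all caught by the downstream 3-SD screen", {
  spec <- small_spec(); spec$outlier_rate <- 0.01
  degraded <- degrade_panel(small_panel(), spec)
  gt <- attr(degraded, "ground_truth")
  out_cells <- gt[gt$kind == "outlier", ]
  expect_gt(nrow(out_cells), 50)
  screened <- screen_outliers(degraded, preprocess_config(outlier_k = 3))
  flagged <- paste(screened$flags$athlete_id, screened$flags$time_index,
                   screened$flags$feature)
  injected <- paste(out_cells$athlete_id, out_cells$time_index,
                    out_cells$feature)
  expect_true(all(injected %in% flagged))
})

test_that("invalid specs are rejected with configuration errors", {
  expect_error(cohort_spec(missing_rate = 0.25), "missing_rate")
  expect_error(cohort_spec(n_per_group = c(high_carb = 0, high_protein = 5,
                                           balanced = 5)), "positive")
  prof <- default_baseline_profiles()
  prof$fatigue$sd[] <- 0
  expect_error(cohort_spec(baseline_profiles = prof), "SD")
})
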