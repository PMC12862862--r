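# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small default-calibration cohort (60 athletes, T = 24) for generator and
# inference tests.
small_spec <- function(seed = 1) {
  cohort_spec(n_per_group = c(high_carb = 20, high_protein = 20,
                              balanced = 20), seed = seed)
}

small_panel <- function() {
  fixture("small_panel", function() generate_cohort(small_spec()))
}

# Full-size cohort (200 athletes) for calibration checks.
full_panel <- function() {
  fixture("full_panel", function() generate_cohort(cohort_spec(seed = 42)))
}

# A hand-built panel whose group means/SDs are exact: two athletes per
# group at mean -/+ sd, so summary arithmetic reproduces reported values
# exactly.
exact_change_panel <- function(groups, baseline_mean, baseline_sd,
                               endpoint_mean, endpoint_sd,
                               outcome = "fatigue") {
  rows <- list()
  for (i in seq_along(groups)) {
    for (s in c(-1, 1)) {
      id <- sprintf("%s_%d", groups[i], (s + 1) / 2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        athlete_id = id, group = groups[i],
        time_index = c(0L, 23L), feature = outcome,
        value = c(baseline_mean[i] + s * baseline_sd[i],
                  endpoint_mean[i] + s * endpoint_sd[i]))
    }
  }
  dplyr::bind_rows(rows)
}

# Panel in which feature b equals feature a shifted by `lag` steps
# (deterministic), for lag-scan construction tests.
shifted_pair_panel <- function(n_athletes = 12, tt = 20, lag = 3) {
  set.seed(99)
  rows <- lapply(seq_len(n_athletes), function(i) {
    a <- cumsum(rnorm(tt + lag))
    tibble::tibble(
      athlete_id = sprintf("S%02d", i), group = "balanced",
      time_index = rep(0:(tt - 1), 2),
      feature = rep(c("a", "b"), each = tt),
      value = c(a[(lag + 1):(tt + lag)], a[1:tt]))
  })
  dplyr::bind_rows(rows)
}
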