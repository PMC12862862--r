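#' Build a cohort spec from a pipeline configuration list
#'
#' Accepts the `cohort:` section of a pipeline YAML config; scalar fields
#' override [cohort_spec()] defaults, calibration tables stay at their
#' defaults.
#'
#' @param cfg Named list (possibly empty).
#' @return A [cohort_spec()].
#' @export
cohort_spec_from_config <- function(cfg = list()) {
  args <- list()
  for (nm in c("n_timepoints", "lag_steps", "missing_rate", "outlier_rate",
               "noise_scale", "ar_phi", "ar_sd", "lag_gain", "seed")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  if (!is.null(cfg$n_per_group)) {
    args$n_per_group <- unlist(cfg$n_per_group)[DIET_GROUPS]
  }
  do.call(cohort_spec, args)
}

pipeline_config_schema <- c("cohort", "preprocess", "split", "model",
                            "analysis")

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("pipeline config must be a YAML mapping",
                          call. = FALSE)
  unknown <- setdiff(names(cfg), pipeline_config_schema)
  if (length(unknown)) {
    stop("pipeline config: unknown key(s): ", paste(unknown, collapse = ", "),
         "; expected a subset of: ",
         paste(pipeline_config_schema, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort generation, degradation, outlier screening,
#' imputation, temporal split, normalisation (fit on training athletes),
#' hybrid model training and evaluation, Shapley attribution, serial
#' mediation, lag-correlation scan, canonical correlation, and subgroup
#' summaries. Writes the table-shaped CSV reports, a JSON summary, a JSON
#' run manifest, and a JSON-lines stage log into `out_dir`.
#'
#' @param config Path to a YAML config or an equivalent named list.
#'   Sections (all optional): `cohort`, `preprocess`, `split`, `model`
#'   (`profile`, `outcome`, `mcid`, `temporal`, `boost`), `analysis`
#'   (`max_lag`, `n_boot`, `shap_athletes`).
#' @param out_dir Output directory (created if needed).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  t_start <- Sys.time()
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  timings <- list()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- fun()
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[name]] <<- el
    cat(jsonlite::toJSON(list(stage = name, seconds = round(el, 2),
                              time = format(Sys.time())), auto_unbox = TRUE),
        "\n", file = log_path, append = TRUE)
    res
  }

  spec <- cohort_spec_from_config(config$cohort)
  panel <- stage("generate", function() generate_cohort(spec))
  stage("write_panel", function()
    write_panel(panel, file.path(out_dir, "panel.csv"), spec))

  pp_cfg <- do.call(preprocess_config, config$preprocess %||% list())
  screened <- stage("screen_outliers", function()
    screen_outliers(panel, pp_cfg))
  completed <- stage("impute", function()
    impute_chained(screened$panel, pp_cfg))

  split_args <- config$split %||% list()
  plan <- stage("split", function()
    do.call(make_temporal_split, c(list(panel = completed), split_args)))
  jsonlite::write_json(
    list(train_athletes = plan$train_athletes,
         test_athletes = plan$test_athletes, folds = plan$folds,
         gap_steps = plan$gap_steps, window = plan$window),
    file.path(out_dir, "split_plan.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  normalized <- stage("normalize", function()
    normalize_features(completed, pp_cfg,
                       train_athletes = plan$train_athletes))
  engineered <- stage("engineer", function() engineer_features(normalized))
  write_panel(engineered, file.path(out_dir, "panel_processed.csv"))

  mdl <- config$model %||% list()
  outcome <- mdl$outcome %||% "fatigue"
  profile <- mdl$profile %||% "desk"
  t_cfg <- do.call(temporal_branch_config,
                   c(list(profile = profile), mdl$temporal %||% list()))
  b_cfg <- do.call(boost_branch_config,
                   c(list(profile = profile), mdl$boost %||% list()))
  hybrid <- stage("train", function()
    train_hybrid(normalized, plan, outcome = outcome,
                 temporal_config = t_cfg, boost_config = b_cfg,
                 raw_panel = completed, mcid = mdl$mcid %||% 1.0))
  report <- stage("evaluate", function() evaluate_hybrid(hybrid))
  branch_cmp <- compare_branches(hybrid)
  metrics <- tibble::tibble(
    model = branch_cmp$model, rmse = branch_cmp$rmse,
    auc = c(NA, NA, report$auc), sensitivity = c(NA, NA, report$sensitivity),
    specificity = c(NA, NA, report$specificity))
  utils::write.csv(metrics, file.path(out_dir, "model_metrics.csv"),
                   row.names = FALSE)

  an <- config$analysis %||% list()
  shap_n <- an$shap_athletes %||% 40
  imp <- stage("explain", function() {
    set.seed(spec$seed)
    ids <- sort(sample(plan$train_athletes,
                       min(shap_n, length(plan$train_athletes))))
    shap_response_importance(completed, athletes = ids, outcome = outcome,
                             config = b_cfg, seed = spec$seed)
  })
  utils::write.csv(as.data.frame(imp),
                   file.path(out_dir, "shap_importance.csv"),
                   row.names = FALSE)

  med <- stage("mediate", function() {
    scores <- athlete_change_scores(completed)
    fit_mediation_serial(scores, exposure = "x", mediators = c("m1", "m2"),
                         outcome = "y", n_boot = an$n_boot %||% 1000,
                         seed = spec$seed)
  })
  utils::write.csv(med$paths, file.path(out_dir, "mediation_paths.csv"),
                   row.names = FALSE)

  lag_pairs <- list(c("fatigue", "il6"), c("stress", "tnf_alpha"),
                    c("resilience", "iga"))
  lags <- stage("lag_scan", function() {
    lapply(lag_pairs, function(p)
      lag_correlation_scan(completed, p[1], p[2],
                           max_lag = an$max_lag %||% 6,
                           n_boot = 100, seed = spec$seed))
  })
  lag_tab <- dplyr::bind_rows(lapply(lags, function(l)
    tibble::tibble(series_a = l$series_a, series_b = l$series_b,
                   peak_lag = l$peak_lag, peak_months = l$peak_months,
                   peak_r = l$peak_r)))
  utils::write.csv(lag_tab, file.path(out_dir, "lag_correlations.csv"),
                   row.names = FALSE)

  base_wide <- panel_wide(dplyr::filter(completed, .data$time_index == 0))
  cca <- first_canonical_correlation(
    base_wide[, c("fatigue", "stress", "sleep_quality", "resilience")],
    base_wide[, c("il6", "tnf_alpha", "crp", "iga")])

  changes <- stage("subgroup", function() {
    dplyr::bind_rows(lapply(c("fatigue", "stress", "resilience", "cortisol"),
                            function(oc) summarize_change(completed, oc)))
  })
  utils::write.csv(changes, file.path(out_dir, "group_changes.csv"),
                   row.names = FALSE)
  profiles <- subgroup_profiles(completed)
  utils::write.csv(profiles, file.path(out_dir, "subgroup_profiles.csv"),
                   row.names = FALSE)

  summary <- list(
    n_athletes = length(unique(panel$athlete_id)),
    n_train = length(plan$train_athletes),
    n_test = length(plan$test_athletes),
    tertile_sizes = as.list(table(panel_athletes(panel)$tertile)),
    canonical_r1 = cca$r1,
    mediation_proportion_pct = med$proportion_mediated,
    indirect_serial = med$indirect_serial,
    lag_peaks = lag_tab,
    model_metrics = metrics,
    top_shap_features = utils::head(imp$feature, 5))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pniflow")),
    config_hash = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    seed = spec$seed,
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outputs = union(list.files(out_dir), "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
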