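#' Long/wide views of an athlete panel
#'
#' The canonical in-memory form of a panel is a long tibble with columns
#' `athlete_id`, `group`, `tertile`, `time_index`, `feature`, `value`.
#' `panel_wide()` pivots it to one row per (athlete, time) with one column
#' per feature; `panel_long()` is the inverse.
#'
#' @param panel Long-format panel tibble.
#' @return A tibble.
#' @export
panel_wide <- function(panel) {
  check_panel(panel)
  tidyr::pivot_wider(panel, names_from = "feature", values_from = "value") |>
    dplyr::arrange(.data$athlete_id, .data$time_index)
}

#' @rdname panel_wide
#' @param wide Wide-format panel as produced by [panel_wide()].
#' @export
panel_long <- function(wide) {
  id_cols <- intersect(c("athlete_id", "group", "tertile", "time_index"),
                       names(wide))
  tidyr::pivot_longer(wide, cols = -dplyr::all_of(id_cols),
                      names_to = "feature", values_to = "value")
}

check_panel <- function(panel) {
  needed <- c("athlete_id", "group", "time_index", "feature", "value")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    stop("not an athlete panel: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- anyDuplicated(panel[c("athlete_id", "time_index", "feature")])
  if (dup) {
    stop("athlete panel has duplicated (athlete_id, time_index, feature) rows",
         call. = FALSE)
  }
  invisible(panel)
}

#' Feature names present in a panel
#' @param panel Long-format panel.
#' @export
panel_features <- function(panel) unique(panel$feature)

#' Athlete-level metadata (id, group, tertile)
#' @param panel Long-format panel.
#' @export
panel_athletes <- function(panel) {
  dplyr::distinct(panel, .data$athlete_id, .data$group,
                  dplyr::across(dplyr::any_of("tertile")))
}

#' Write / read a panel as CSV with a JSON sidecar
#'
#' The CSV carries the long-format rows; the sidecar records the generating
#' spec, the seed, and (for degraded panels) the ground-truth mask of
#' injected missing cells and outliers.
#'
#' @param panel Long-format panel.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param spec Optional [cohort_spec()] to record in the sidecar.
#' @export
write_panel <- function(panel, path, spec = NULL) {
  check_panel(panel)
  out <- panel
  out$value <- format_value_stable(out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    n_athletes = length(unique(panel$athlete_id)),
    n_timepoints = length(unique(panel$time_index)),
    features = panel_features(panel)
  )
  if (!is.null(spec)) {
    sidecar$spec <- unclass(spec)
    sidecar$seed <- spec$seed
  }
  gt <- attr(panel, "ground_truth")
  if (!is.null(gt)) sidecar$ground_truth <- gt
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Fixed-precision formatting so identical panels are byte-identical on disk.
format_value_stable <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  panel$value <- as.numeric(panel$value)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$ground_truth)) {
      attr(panel, "ground_truth") <- tibble::as_tibble(sc$ground_truth)
    }
  }
  check_panel(panel)
  panel
}
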