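GAUGE_METRICS <- c(completion_time = "duration", force_range = "range",
                   variability_index = "fluctuation",
                   uncertainty_index = "spectral_entropy")

#' Expert baseline for the performance gauges
#'
#' Four representative measures summarize a surgeon's force profile on
#' the dashboard: task completion time (the `duration` feature, seconds),
#' range of force application (`range`, Newtons), the force variability
#' index (`fluctuation`) and the force uncertainty index
#' (`spectral_entropy`, the level of entropy in the time series). The
#' baseline is the mean and sample SD of each measure over all Expert
#' segments; Novice rows are ignored.
#'
#' @param features A [extract_features()] table containing Expert rows.
#' @return An object of class `expert_baseline`: per metric `mean` and
#'   `sd`, plus `n_expert_segments`.
#' @export
compute_baseline <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  ex <- features[features$experience == "Expert", , drop = FALSE]
  if (nrow(ex) == 0L)
    stop("baseline error: no Expert segments in the feature table")
  metrics <- lapply(GAUGE_METRICS, function(col) {
    v <- ex[[col]]
    v <- v[is.finite(v)]
    list(mean = mean(v), sd = if (length(v) >= 2L) sd(v) else 0)
  })
  structure(list(metrics = metrics, n_expert_segments = nrow(ex)),
            class = "expert_baseline")
}

#' @export
print.expert_baseline <- function(x, ...) {
  cat(sprintf("<expert_baseline> from %d expert segments\n",
              x$n_expert_segments))
  for (m in names(x$metrics))
    cat(sprintf("  %-18s %.4g (sd %.4g)\n", m, x$metrics[[m]]$mean,
                x$metrics[[m]]$sd))
  invisible(x)
}

#' Per-surgeon performance gauge panel
#'
#' For one surgeon over a selected range of cases, each gauge metric is
#' the unweighted mean of the feature over the surgeon's segments in
#' those cases, reported next to the expert mean and SD with a z-score
#' `(surgeon_value - expert_mean) / expert_sd` (not available when the
#' expert SD is zero). The baseline is never altered by panel
#' construction.
#'
#' @param features A [extract_features()] table.
#' @param surgeon_id Surgeon to report on.
#' @param baseline A [compute_baseline()] result.
#' @param case_range Optional character vector of case ids to include;
#'   `NULL` means all of the surgeon's cases.
#' @return An object of class `gauge_panel`: `surgeon_id`, `case_range`,
#'   `n_segments` and a `metrics` data frame (`metric`, `surgeon_value`,
#'   `expert_mean`, `expert_sd`, `z_score`).
#' @export
gauge_panel <- function(features, surgeon_id, baseline, case_range = NULL) {
  stopifnot(inherits(features, "feature_table"),
            inherits(baseline, "expert_baseline"))
  rows <- features[features$surgeon_id == surgeon_id, , drop = FALSE]
  if (!is.null(case_range))
    rows <- rows[rows$case_id %in% case_range, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("empty selection: surgeon %s has no segments in case range [%s]",
                 surgeon_id,
                 if (is.null(case_range)) "all"
                 else paste(case_range, collapse = ", ")))
  met <- do.call(rbind, lapply(names(GAUGE_METRICS), function(m) {
    v <- rows[[GAUGE_METRICS[[m]]]]
    v <- v[is.finite(v)]
    sv <- if (length(v)) mean(v) else NA_real_
    em <- baseline$metrics[[m]]$mean
    es <- baseline$metrics[[m]]$sd
    data.frame(metric = m, surgeon_value = sv, expert_mean = em,
               expert_sd = es,
               z_score = if (is.finite(sv) && es > 0) (sv - em) / es
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(surgeon_id = surgeon_id,
                 case_range = if (is.null(case_range))
                   sort(unique(rows$case_id)) else case_range,
                 n_segments = nrow(rows), metrics = met),
            class = "gauge_panel")
}

#' @export
print.gauge_panel <- function(x, ...) {
  cat(sprintf("<gauge_panel> surgeon %s, %d segments over %d case(s)\n",
              x$surgeon_id, x$n_segments, length(x$case_range)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Write a gauge panel as JSON
#'
#' Emits a structure directly renderable by a dashboard front end.
#'
#' @param panel A [gauge_panel()] result.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_gauge_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gauge_panel"))
  jsonlite::write_json(
    list(surgeon_id = panel$surgeon_id, case_range = panel$case_range,
         n_segments = panel$n_segments, metrics = panel$metrics),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
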