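#' Butterworth low-pass filter specification
#'
#' The default preprocessing filter is a digital 4th-order Butterworth
#' low-pass with a 0.1 Hz cutoff, applied in zero-phase (forward-backward)
#' mode. The cutoff is an absolute frequency in Hertz and must stay below
#' the Nyquist frequency of the segment it is applied to; both cutoff and
#' sampling rate are explicit configuration, never assumed.
#'
#' @param order Filter order, >= 1. Default 4.
#' @param cutoff Cutoff frequency in Hz. Default 0.1.
#' @param mode `"zero_phase"` (two passes, no phase lag; squared magnitude
#'   response, so gain 1/2 at the cutoff) or `"causal"` (single forward
#'   pass, for streaming parity).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff = 0.1,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1 || order != round(order))
    stop("filter order must be a positive integer")
  if (cutoff <= 0)
    stop("filter cutoff must be positive")
  structure(list(order = as.integer(order), cutoff = cutoff, mode = mode),
            class = "filter_spec")
}

# minimum segment length for zero-phase filtering: the odd-reflection pad
# on each side is 3 * (number of filter coefficients)
filtfilt_padlen <- function(order) 3L * (2L * as.integer(order) + 1L)

#' Smooth a force segment
#'
#' Both prongs are passed through the Butterworth low-pass filter of
#' `spec`. Zero-phase mode uses steady-state initial conditions and
#' odd-reflection padding at both ends, so constant signals are preserved
#' exactly and there is no start-up transient or phase lag.
#'
#' @param seg A [force_segment()].
#' @param spec A [filter_spec()]; `cutoff` must be below the segment's
#'   Nyquist frequency.
#' @return The segment with both force channels filtered; the applied
#'   filter is recorded in `seg$filtered`.
#' @export
smooth_segment <- function(seg, spec = filter_spec()) {
  stopifnot(inherits(seg, "force_segment"), inherits(spec, "filter_spec"))
  nyq <- seg$sampling_rate / 2
  if (spec$cutoff >= nyq)
    stop(sprintf("filter parameter error: cutoff %.6g Hz >= Nyquist %.6g Hz",
                 spec$cutoff, nyq))
  n <- length(seg$right_force)
  if (spec$mode == "zero_phase") {
    padlen <- filtfilt_padlen(spec$order)
    if (n <= padlen)
      stop(sprintf("segment too short for zero-phase filtering: need at least %d samples, got %d",
                   padlen + 1L, n))
  }
  ba <- signal::butter(spec$order, spec$cutoff / nyq, type = "low")
  apply1 <- function(x) {
    if (spec$mode == "zero_phase")
      .iir_filtfilt(ba$b, ba$a, x, filtfilt_padlen(spec$order))
    else
      .iir_filter(ba$b, ba$a, x)
  }
  seg$left_force <- apply1(seg$left_force)
  seg$right_force <- apply1(seg$right_force)
  seg$filtered <- sprintf("butterworth(order=%d, cutoff=%.6g Hz, %s)",
                          spec$order, spec$cutoff, spec$mode)
  seg
}

#' Smooth every segment of a table
#'
#' @param table A [segment_table()].
#' @param spec A [filter_spec()].
#' @return The filtered table; provenance is extended.
#' @export
smooth_segments <- function(table, spec = filter_spec()) {
  stopifnot(inherits(table, "segment_table"))
  out <- lapply(table$segments, smooth_segment, spec = spec)
  segment_table(out, provenance = paste0(table$provenance, " | smoothed ",
                                         spec$mode))
}

# per-segment statistics entering the outlier rule
segment_outlier_stats <- function(seg, channel = "right") {
  x <- analysis_channel(seg, channel)
  c(max_force = max(x), min_force = min(x), duration = seg$duration)
}

#' Derive expert percentile thresholds
#'
#' Over all Expert segments, the per-segment maximum force, minimum force
#' and task completion time are collected and their 1st and 99th
#' percentiles (linear-interpolation definition) form the acceptance
#' bands: experienced surgeons are assumed to produce fewer than 1% of
#' segments in error, so values outside these bands mark candidate
#' outliers.
#'
#' @param table A [segment_table()] containing at least 2 Expert segments
#'   (ideally already smoothed).
#' @param channel Analysis channel: `"right"` (default), `"left"` or
#'   `"max"` (elementwise maximum of the prongs).
#' @return An object of class `expert_thresholds` with fields
#'   `max_force_p1/p99`, `min_force_p1/p99`, `duration_p1/p99` and
#'   `n_expert_segments`.
#' @export
fit_expert_thresholds <- function(table, channel = "right") {
  stopifnot(inherits(table, "segment_table"))
  experts <- Filter(function(s) s$experience == "Expert", table$segments)
  if (length(experts) < 2L)
    stop("fitting error: need at least 2 Expert segments to derive thresholds")
  stats <- t(vapply(experts, segment_outlier_stats, numeric(3),
                    channel = channel))
  q <- apply(stats, 2, quantile, probs = c(0.01, 0.99), type = 7,
             names = FALSE)
  structure(list(max_force_p1 = unname(q[1, "max_force"]),
                 max_force_p99 = unname(q[2, "max_force"]),
                 min_force_p1 = unname(q[1, "min_force"]),
                 min_force_p99 = unname(q[2, "min_force"]),
                 duration_p1 = unname(q[1, "duration"]),
                 duration_p99 = unname(q[2, "duration"]),
                 n_expert_segments = length(experts),
                 channel = channel),
            class = "expert_thresholds")
}

#' @export
print.expert_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<expert_thresholds> (%d expert segments, %s prong)\n",
                     "  max force  [%.4g, %.4g] N\n",
                     "  min force  [%.4g, %.4g] N\n",
                     "  duration   [%.4g, %.4g] s\n"),
              x$n_expert_segments, x$channel,
              x$max_force_p1, x$max_force_p99,
              x$min_force_p1, x$min_force_p99,
              x$duration_p1, x$duration_p99))
  invisible(x)
}

#' Serialize / read expert thresholds as JSON
#' @param thr An `expert_thresholds` object.
#' @param path JSON file path.
#' @return `path` invisibly, or the read object.
#' @export
write_thresholds <- function(thr, path) {
  stopifnot(inherits(thr, "expert_thresholds"))
  jsonlite::write_json(unclass(thr), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path)
  structure(lapply(x, function(v) if (is.character(v)) v else as.numeric(v)),
            class = "expert_thresholds")
}

#' Flag outlier segments against expert thresholds
#'
#' A segment is flagged iff any of its maximum force, minimum force or
#' duration falls outside the corresponding expert `[p1, p99]` interval.
#' Flagging is separated from removal so the decision is auditable.
#'
#' @param table A [segment_table()].
#' @param thr An [fit_expert_thresholds()] result.
#' @return A data frame with one row per segment: `segment_id`, `flagged`,
#'   and `reasons` (';'-joined tokens among `max_force_high/low`,
#'   `min_force_high/low`, `duration_high/low`; empty when kept).
#' @export
flag_outliers <- function(table, thr) {
  stopifnot(inherits(table, "segment_table"),
            inherits(thr, "expert_thresholds"))
  rows <- lapply(table$segments, function(s) {
    st <- segment_outlier_stats(s, thr$channel)
    reasons <- character(0)
    if (st["max_force"] > thr$max_force_p99) reasons <- c(reasons, "max_force_high")
    if (st["max_force"] < thr$max_force_p1) reasons <- c(reasons, "max_force_low")
    if (st["min_force"] > thr$min_force_p99) reasons <- c(reasons, "min_force_high")
    if (st["min_force"] < thr$min_force_p1) reasons <- c(reasons, "min_force_low")
    if (st["duration"] > thr$duration_p99) reasons <- c(reasons, "duration_high")
    if (st["duration"] < thr$duration_p1) reasons <- c(reasons, "duration_low")
    data.frame(segment_id = s$segment_id,
               flagged = length(reasons) > 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove flagged outlier segments
#'
#' Pure filter over [flag_outliers()] output.
#'
#' @param table A [segment_table()].
#' @param flags Data frame from [flag_outliers()] on the same table.
#' @return The table restricted to unflagged segments.
#' @export
remove_outliers <- function(table, flags) {
  stopifnot(inherits(table, "segment_table"))
  keep <- flags$segment_id[!flags$flagged]
  segs <- Filter(function(s) s$segment_id %in% keep, table$segments)
  segment_table(segs, provenance = paste0(
    table$provenance,
    sprintf(" | removed %d/%d outlier segments", sum(flags$flagged),
            nrow(flags))))
}
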