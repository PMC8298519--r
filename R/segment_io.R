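#' @useDynLib forcetrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd var approx coef lm qt shapiro.test
#'   aov TukeyHSD rnorm rlnorm runif predict acf fft
#' @importFrom utils read.csv write.csv head
NULL

#' The closed set of surgical task labels
#'
#' The five annotated manoeuvre classes recognised throughout the pipeline:
#' Retracting (grasping and retaining tissue for exposure), Manipulation
#' (moving cotton or other non-tissue material), Dissecting, Pulling and
#' Coagulation. Any other label is rejected at parse time.
#'
#' @export
TASK_LEVELS <- c("Retracting", "Manipulation", "Dissecting", "Pulling",
                 "Coagulation")

#' Experience labels
#' @export
EXPERIENCE_LEVELS <- c("Expert", "Novice")

EVENT_FLAGS <- c("high_force_error", "low_force_error", "bleeding",
                 "repeat_task")

#' Construct a validated two-prong force recording
#'
#' A recording holds the left and right prong contact forces (Newtons)
#' sampled on a common, strictly increasing time base (seconds from
#' recording start).
#'
#' @param case_id Case identifier.
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing, length at least 2.
#' @param left_force,right_force Numeric force vectors (N), same length as
#'   `time`, all finite.
#' @param sampling_rate Samples per second. If `NULL`, inferred as
#'   `1 / median(diff(time))`. The median time step must be within 1% of
#'   `1 / sampling_rate`.
#' @param metadata Optional named list (surgeon_id, date, pathology, ...).
#' @return An object of class `force_recording`.
#' @export
force_recording <- function(case_id, time, left_force, right_force,
                            sampling_rate = NULL, metadata = list()) {
  time <- as.numeric(time)
  left_force <- as.numeric(left_force)
  right_force <- as.numeric(right_force)
  if (length(time) < 2L)
    stop("a force recording needs at least 2 samples")
  if (length(left_force) != length(time) ||
      length(right_force) != length(time))
    stop("time, left_force and right_force must have equal length")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("time must be finite and strictly increasing")
  if (any(!is.finite(left_force)) || any(!is.finite(right_force)))
    stop("force values must be finite")
  dt <- median(diff(time))
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / dt
  } else {
    sampling_rate <- as.numeric(sampling_rate)
    if (abs(dt - 1 / sampling_rate) > 0.01 / sampling_rate)
      stop("median time step deviates more than 1% from 1/sampling_rate")
  }
  structure(list(case_id = as.character(case_id),
                 sampling_rate = sampling_rate,
                 time = time,
                 left_force = left_force,
                 right_force = right_force,
                 metadata = metadata),
            class = "force_recording")
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> case %s: %d samples at %.6g Hz (%.2f s)\n",
              x$case_id, length(x$time), x$sampling_rate,
              x$time[length(x$time)] - x$time[1]))
  invisible(x)
}

#' Read a force recording from CSV
#'
#' Expects header columns `time_s,left_force_n,right_force_n` (UTF-8,
#' '.' decimal separator).
#'
#' @param path CSV file path.
#' @param case_id Case identifier; defaults to the file name without
#'   extension.
#' @param sampling_rate_override If given, used instead of the rate
#'   inferred from the median time step.
#' @return A [force_recording()].
#' @export
read_recording <- function(path, case_id = NULL,
                           sampling_rate_override = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "left_force_n", "right_force_n")
  if (!all(need %in% names(df)))
    stop("recording format error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(case_id))
    case_id <- tools::file_path_sans_ext(basename(path))
  force_recording(case_id, df$time_s, df$left_force_n, df$right_force_n,
                  sampling_rate = sampling_rate_override)
}

#' Write a force recording to CSV
#'
#' @param rec A [force_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "force_recording"))
  df <- data.frame(time_s = rec$time, left_force_n = rec$left_force,
                   right_force_n = rec$right_force)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a segment annotation table
#'
#' @param start,end Segment boundaries in recording time (seconds);
#'   `start < end` per row.
#' @param task Task labels drawn from [TASK_LEVELS].
#' @param surgeon_id Surgeon identifiers.
#' @param experience `"Expert"` or `"Novice"`.
#' @param pgy_band Optional post-graduate-year band (free text).
#' @param event_flags Optional list of character vectors with entries among
#'   `high_force_error`, `low_force_error`, `bleeding`, `repeat_task`.
#' @return A `data.frame` of class `segment_annotation`.
#' @export
segment_annotation <- function(start, end, task, surgeon_id, experience,
                               pgy_band = NA_character_,
                               event_flags = NULL) {
  n <- length(start)
  task <- as.character(task)
  experience <- as.character(experience)
  if (any(end <= start))
    stop("annotation validation error: start must be < end")
  if (!all(task %in% TASK_LEVELS))
    stop("annotation validation error: unknown task label(s): ",
         paste(setdiff(unique(task), TASK_LEVELS), collapse = ", "))
  if (!all(experience %in% EXPERIENCE_LEVELS))
    stop("annotation validation error: experience must be Expert or Novice")
  if (is.null(event_flags)) event_flags <- rep(list(character(0)), n)
  bad <- setdiff(unlist(event_flags), EVENT_FLAGS)
  if (length(bad))
    stop("annotation validation error: unknown event flag(s): ",
         paste(bad, collapse = ", "))
  out <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    task = task,
                    surgeon_id = as.character(surgeon_id),
                    experience = experience,
                    pgy_band = rep_len(as.character(pgy_band), n),
                    stringsAsFactors = FALSE)
  out$event_flags <- I(event_flags)
  class(out) <- c("segment_annotation", "data.frame")
  out
}

#' Read segment annotations from CSV
#'
#' Expects columns `start_s,end_s,task,surgeon_id,experience,pgy_band,
#' event_flags`, `event_flags` being ';'-separated tokens (may be empty).
#'
#' @param path CSV file path.
#' @return A [segment_annotation()] table.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "task", "surgeon_id", "experience")
  if (!all(need %in% names(df)))
    stop("annotation format error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  flags <- if ("event_flags" %in% names(df)) {
    lapply(df$event_flags, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  } else NULL
  segment_annotation(df$start_s, df$end_s, df$task, df$surgeon_id,
                     df$experience,
                     pgy_band = if ("pgy_band" %in% names(df)) df$pgy_band
                                else NA_character_,
                     event_flags = flags)
}

#' Construct a single force segment
#'
#' A segment is one annotated, contiguous episode of force application in a
#' specific surgical task: the pipeline's unit of analysis.
#'
#' @param segment_id Unique identifier.
#' @param case_id Originating case.
#' @param sampling_rate Samples per second.
#' @param left_force,right_force Force samples (N), non-empty, finite,
#'   equal length.
#' @param task,surgeon_id,experience,pgy_band,event_flags Metadata as in
#'   [segment_annotation()].
#' @return An object of class `force_segment`.
#' @export
force_segment <- function(segment_id, case_id, sampling_rate,
                          left_force, right_force, task, surgeon_id,
                          experience, pgy_band = NA_character_,
                          event_flags = character(0)) {
  left_force <- as.numeric(left_force)
  right_force <- as.numeric(right_force)
  if (length(left_force) == 0L || length(left_force) != length(right_force))
    stop("segment arrays must be non-empty and of equal length")
  if (any(!is.finite(left_force)) || any(!is.finite(right_force)))
    stop("segment force values must be finite")
  if (!task %in% TASK_LEVELS)
    stop("unknown task label: ", task)
  if (!experience %in% EXPERIENCE_LEVELS)
    stop("experience must be Expert or Novice")
  structure(list(segment_id = as.character(segment_id),
                 case_id = as.character(case_id),
                 sampling_rate = as.numeric(sampling_rate),
                 left_force = left_force,
                 right_force = right_force,
                 task = task,
                 surgeon_id = as.character(surgeon_id),
                 experience = experience,
                 pgy_band = as.character(pgy_band),
                 event_flags = as.character(event_flags),
                 duration = length(left_force) / sampling_rate),
            class = "force_segment")
}

#' @export
print.force_segment <- function(x, ...) {
  cat(sprintf("<force_segment> %s [%s, %s, %s]: %d samples, %.2f s\n",
              x$segment_id, x$task, x$surgeon_id, x$experience,
              length(x$right_force), x$duration))
  invisible(x)
}

#' Construct a segment table
#'
#' An ordered collection of [force_segment()] objects with unique ids,
#' carrying a free-text provenance trail of the files and processing steps
#' that produced it.
#'
#' @param segments List of `force_segment` objects.
#' @param provenance Character description of origin.
#' @return An object of class `segment_table`.
#' @export
segment_table <- function(segments, provenance = "") {
  stopifnot(all(vapply(segments, inherits, TRUE, "force_segment")))
  ids <- vapply(segments, `[[`, "", "segment_id")
  if (anyDuplicated(ids))
    stop("segment_ids must be unique")
  structure(list(segments = segments, provenance = provenance),
            class = "segment_table")
}

#' @export
length.segment_table <- function(x) length(x$segments)

#' @export
print.segment_table <- function(x, ...) {
  tasks <- vapply(x$segments, `[[`, "", "task")
  cat(sprintf("<segment_table> %d segments (%s)\n", length(x$segments),
              paste(sprintf("%s: %d", names(table(tasks)), table(tasks)),
                    collapse = ", ")))
  invisible(x)
}

#' Segment metadata as a data frame
#'
#' @param x A [segment_table()].
#' @param ... Unused.
#' @return One row per segment: id, case, task, surgeon, experience,
#'   duration, n_samples.
#' @export
as.data.frame.segment_table <- function(x, ...) {
  do.call(rbind, lapply(x$segments, function(s)
    data.frame(segment_id = s$segment_id, case_id = s$case_id,
               task = s$task, surgeon_id = s$surgeon_id,
               experience = s$experience, pgy_band = s$pgy_band,
               duration = s$duration,
               n_samples = length(s$right_force),
               stringsAsFactors = FALSE)))
}

#' Cut a recording into force segments along annotation intervals
#'
#' Samples are assigned by the half-open rule: sample `i` belongs to an
#' annotation iff `start + clock_offset <= time[i] < end + clock_offset`,
#' which prevents double-assignment at shared boundaries. The scalar
#' `clock_offset` absorbs any constant clock difference between the
#' annotation source (e.g. an audio track) and the force logger.
#'
#' @param rec A [force_recording()].
#' @param annotations A [segment_annotation()] table; intervals must not
#'   overlap.
#' @param clock_offset Seconds added to annotation times to align them with
#'   the recording clock.
#' @return A [segment_table()]. Annotations capturing fewer than 2 samples
#'   are dropped with a warning.
#' @export
segment_recording <- function(rec, annotations, clock_offset = 0) {
  stopifnot(inherits(rec, "force_recording"),
            inherits(annotations, "segment_annotation"))
  ord <- order(annotations$start)
  ann <- annotations[ord, , drop = FALSE]
  if (nrow(ann) > 1 && any(ann$start[-1] < ann$end[-nrow(ann)]))
    stop("annotation validation error: overlapping annotation intervals")
  segs <- list()
  dropped <- 0L
  for (k in seq_len(nrow(ann))) {
    lo <- ann$start[k] + clock_offset
    hi <- ann$end[k] + clock_offset
    idx <- which(rec$time >= lo & rec$time < hi)
    if (length(idx) < 2L) {
      dropped <- dropped + 1L
      next
    }
    segs[[length(segs) + 1L]] <- force_segment(
      segment_id = sprintf("%s_seg%03d", rec$case_id, k),
      case_id = rec$case_id, sampling_rate = rec$sampling_rate,
      left_force = rec$left_force[idx], right_force = rec$right_force[idx],
      task = ann$task[k], surgeon_id = ann$surgeon_id[k],
      experience = ann$experience[k], pgy_band = ann$pgy_band[k],
      event_flags = ann$event_flags[[k]])
  }
  if (dropped > 0L)
    warning(sprintf("%d annotation(s) dropped: fewer than 2 samples inside the recording",
                    dropped))
  segment_table(segs, provenance = sprintf(
    "segment_recording(case %s, %d annotations, clock_offset %.6g s)",
    rec$case_id, nrow(ann), clock_offset))
}

#' Write a segment table to disk
#'
#' Produces a long-format CSV (`segment_id,time_s,left_force_n,
#' right_force_n`) and a JSON sidecar (`<path>.meta.json`) holding the
#' per-segment metadata. The pair round-trips loss-free through
#' [read_segments()].
#'
#' @param table A [segment_table()].
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_segments <- function(table, path) {
  stopifnot(inherits(table, "segment_table"))
  rows <- lapply(table$segments, function(s) {
    n <- length(s$right_force)
    data.frame(segment_id = rep(s$segment_id, n),
               time_s = (seq_len(n) - 1) / s$sampling_rate,
               left_force_n = s$left_force,
               right_force_n = s$right_force)
  })
  long <- if (length(rows)) do.call(rbind, rows)
          else data.frame(segment_id = character(0), time_s = numeric(0),
                          left_force_n = numeric(0),
                          right_force_n = numeric(0))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- lapply(table$segments, function(s)
    list(segment_id = s$segment_id, case_id = s$case_id,
         sampling_rate = s$sampling_rate, task = s$task,
         surgeon_id = s$surgeon_id, experience = s$experience,
         pgy_band = s$pgy_band, event_flags = as.list(s$event_flags)))
  jsonlite::write_json(list(provenance = table$provenance, segments = meta),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "list")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a segment table written by [write_segments()]
#'
#' @param path CSV path; `<path>.meta.json` must exist.
#' @return A [segment_table()].
#' @export
read_segments <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(segment_id = "character"))
  side <- jsonlite::read_json(sidecar_path(path))
  meta <- side$segments
  ids_meta <- vapply(meta, `[[`, "", "segment_id")
  ids_csv <- unique(long$segment_id)
  if (!setequal(ids_meta, ids_csv))
    stop("segment format error: metadata/sample segment_id mismatch")
  segs <- lapply(meta, function(m) {
    rows <- long[long$segment_id == m$segment_id, , drop = FALSE]
    force_segment(m$segment_id, m$case_id, m$sampling_rate,
                  rows$left_force_n, rows$right_force_n, m$task,
                  m$surgeon_id, m$experience,
                  pgy_band = if (is.null(m$pgy_band)) NA_character_
                             else m$pgy_band,
                  event_flags = unlist(m$event_flags))
  })
  segment_table(segs, provenance = if (is.null(side$provenance)) ""
                                   else side$provenance)
}

# right / left / elementwise max of the two prongs
analysis_channel <- function(seg, channel = c("right", "left", "max")) {
  channel <- match.arg(channel)
  switch(channel,
         right = seg$right_force,
         left = seg$left_force,
         max = pmax(seg$left_force, seg$right_force))
}
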