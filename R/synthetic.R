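#' Default task/experience profile specification
#'
#' One row per (task, experience) cell giving the segment count, the
#' duration and force-range moments, the baseline force, the task motif
#' and the experience-dependent noise scale and peak multiplier. The
#' defaults reproduce the summary statistics of the clinical force corpus
#' this pipeline was designed around: per-task completion times of
#' 12.1 (7.2) s for Coagulation, 7.6 (5.3) Pulling, 5.4 (2.5)
#' Manipulation, 10.1 (8.6) Dissecting and 7.6 (5.1) Retracting; force
#' ranges of 0.7 (0.5), 1.0 (0.6), 1.2 (0.5), 0.9 (0.5) and 0.7 (0.4) N
#' respectively; and cell counts of 1108/977 (Coagulation Expert/Novice),
#' 192/111 (Pulling), 210/86 (Manipulation), 64/25 (Dissecting) and 71/51
#' (Retracting) — 1645 Expert and 1250 Novice segments in total. The
#' experience contrast is injected through the noise scale (novices
#' noisier, raising within-segment SD and entropy) and a peak multiplier
#' (novice peak forces scaled by 0.39/0.35 relative to experts).
#'
#' @return A `data.frame` of class `task_profile_spec`.
#' @export
default_task_profiles <- function() {
  base <- data.frame(
    task = c("Coagulation", "Pulling", "Manipulation", "Dissecting",
             "Retracting"),
    duration_mean = c(12.1, 7.6, 5.4, 10.1, 7.6),
    duration_sd = c(7.2, 5.3, 2.5, 8.6, 5.1),
    range_mean = c(0.7, 1.0, 1.2, 0.9, 0.7),
    range_sd = c(0.5, 0.6, 0.5, 0.5, 0.4),
    baseline_force = 0.2,
    motif = c("sustained_plateau", "ramp_pull", "oscillatory",
              "burst_train", "grasp_hold"),
    n_expert = c(1108L, 192L, 210L, 64L, 71L),
    n_novice = c(977L, 111L, 86L, 25L, 51L),
    stringsAsFactors = FALSE)
  spec <- do.call(rbind, lapply(c("Expert", "Novice"), function(exp) {
    df <- base[, c("task", "duration_mean", "duration_sd", "range_mean",
                   "range_sd", "baseline_force", "motif")]
    df$experience <- exp
    df$n_segments <- if (exp == "Expert") base$n_expert else base$n_novice
    df$noise_sd <- if (exp == "Expert") 0.04 else 0.10
    df$peak_scale <- if (exp == "Expert") 1.0 else 0.39 / 0.35
    df
  }))
  rownames(spec) <- NULL
  class(spec) <- c("task_profile_spec", "data.frame")
  spec
}

# log-normal parameters matched to a target mean and SD
lnorm_params <- function(m, s) {
  if (s <= 0) return(c(meanlog = log(m), sdlog = 0))
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# unit-amplitude motif shapes over normalized time u in [0, 1]
motif_shape <- function(name, u) {
  switch(name,
    sustained_plateau = 0.5 * (tanh(15 * (u - 0.08)) -
                                 tanh(15 * (u - 0.92))),
    grasp_hold = pmin(u / 0.08, 1) * exp(-1.2 * pmax(u - 0.1, 0)) *
      (1 - pmin(pmax(u - 0.92, 0) / 0.08, 1)),
    oscillatory = (0.55 + 0.45 * sin(2 * pi * 5 * u)) * sin(pi * u)^0.5,
    ramp_pull = ifelse(u < 0.85, (u / 0.85)^1.2, (1 - u) / 0.15),
    burst_train = {
      centers <- c(0.15, 0.38, 0.61, 0.84)
      rowSums(sapply(centers, function(cn) exp(-((u - cn) / 0.05)^2)))
    },
    stop("unknown motif: ", name))
}

#' Generate a synthetic segment table from a profile specification
#'
#' For every (task, experience) cell, `n_segments` force segments are
#' drawn: the duration and force range come from log-normal distributions
#' moment-matched to the cell's mean/SD (both quantities are positive and
#' right-skewed), the task motif is scaled so the noise-free signal spans
#' the drawn range times the experience peak multiplier on top of the
#' baseline force, and Gaussian noise of the cell's `noise_sd` is added.
#' The left prong is generated as a scaled, noisier copy of the right.
#' Generation is fully deterministic given `seed`.
#'
#' @param spec A [default_task_profiles()]-style specification.
#' @param sampling_rate Samples per second. Default 100.
#' @param seed Integer seed.
#' @param min_duration Floor on drawn durations (s). Default 0.25.
#' @return An object of class `synthetic_dataset`: a list with `table`
#'   (a [segment_table()]), `draws` (per-segment drawn duration and
#'   range), `spec` and `seed`.
#' @export
generate_segments <- function(spec = default_task_profiles(),
                              sampling_rate = 100, seed = 1L,
                              min_duration = 0.25) {
  stopifnot(inherits(spec, "task_profile_spec"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  segs <- list()
  draws <- list()
  n_cases <- 10L
  for (ci in seq_len(nrow(spec))) {
    cell <- spec[ci, ]
    if (cell$n_segments == 0L) next
    dp <- lnorm_params(cell$duration_mean, cell$duration_sd)
    rp <- lnorm_params(cell$range_mean, cell$range_sd)
    durs <- pmax(rlnorm(cell$n_segments, dp["meanlog"], dp["sdlog"]),
                 min_duration)
    rngs <- rlnorm(cell$n_segments, rp["meanlog"], rp["sdlog"])
    for (k in seq_len(cell$n_segments)) {
      n <- max(2L, round(durs[k] * sampling_rate))
      u <- (seq_len(n) - 1) / max(n - 1, 1L)
      m <- motif_shape(cell$motif, u)
      m <- (m - min(m)) / max(max(m) - min(m), 1e-12)
      amp <- rngs[k] * cell$peak_scale
      clean <- cell$baseline_force + amp * m
      right <- clean + rnorm(n, 0, cell$noise_sd)
      left <- cell$baseline_force + 0.9 * amp * m +
        rnorm(n, 0, cell$noise_sd * 1.1)
      segs[[length(segs) + 1L]] <- force_segment(
        segment_id = sprintf("%s_%s_%04d", cell$task, cell$experience, k),
        case_id = sprintf("case_%02d", 1L + (length(segs) %% n_cases)),
        sampling_rate = sampling_rate,
        left_force = left, right_force = right,
        task = cell$task,
        surgeon_id = if (cell$experience == "Expert") "S01"
                     else sprintf("S%02d", 1L + sample.int(4L, 1L)),
        experience = cell$experience)
      draws[[length(draws) + 1L]] <- data.frame(
        segment_id = segs[[length(segs)]]$segment_id,
        task = cell$task, experience = cell$experience,
        duration = durs[k], range = rngs[k], stringsAsFactors = FALSE)
    }
  }
  structure(list(table = segment_table(segs, provenance = sprintf(
    "generate_segments(seed = %d, sampling_rate = %g)", seed,
    sampling_rate)),
    draws = do.call(rbind, draws), spec = spec, seed = seed),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> seed %d\n", x$seed))
  print(x$table)
  invisible(x)
}

#' Build a standard synthetic fixture
#'
#' @param profile `"tiny"` (10 segments per task-experience cell, 100
#'   total, for fast tests), `"full"` (the reference cell counts, 2895
#'   segments), or `"tiny_x10"`-style scaling via `n_per_cell`.
#' @param seed Integer seed.
#' @param n_per_cell Overrides the per-cell count (ignored for
#'   `"full"`).
#' @param sampling_rate Samples per second. Default 100.
#' @return A [generate_segments()] dataset.
#' @export
make_fixture <- function(profile = c("tiny", "full"), seed = 1L,
                         n_per_cell = NULL, sampling_rate = 100) {
  profile <- match.arg(profile)
  spec <- default_task_profiles()
  if (profile == "tiny")
    spec$n_segments <- if (is.null(n_per_cell)) 10L
                       else as.integer(n_per_cell)
  generate_segments(spec, sampling_rate = sampling_rate, seed = seed)
}
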