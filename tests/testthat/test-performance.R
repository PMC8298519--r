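# hand-build a minimal feature table for the gauge metrics
gauge_ft <- function(duration, range, fluctuation, entropy, surgeon,
                     experience, case_id = "case_01") {
  n <- length(duration)
  df <- data.frame(segment_id = sprintf("%s_%03d", surgeon, 1:n),
                   case_id = rep_len(case_id, n),
                   task = rep_len(TASK_LEVELS, n),
                   surgeon_id = rep_len(surgeon, n),
                   experience = rep_len(experience, n),
                   stringsAsFactors = FALSE)
  for (f in FEATURE_CATALOGUE) df[[f]] <- NA_real_
  df$duration <- duration
  df$range <- range
  df$fluctuation <- fluctuation
  df$spectral_entropy <- entropy
  class(df) <- c("feature_table", "data.frame")
  df
}

test_that("the expert baseline is the mean/SD of expert segments only", {
  ex <- gauge_ft(c(2, 4), c(1, 1), c(0.2, 0.4), c(0.6, 0.8), "S01", "Expert")
  nv <- gauge_ft(c(100, 200), c(9, 9), c(0.9, 0.9), c(0.99, 0.99), "S02",
                 "Novice")
  both <- rbind(ex, nv)
  class(both) <- c("feature_table", "data.frame")
  b <- compute_baseline(both)
  expect_equal(b$metrics$completion_time$mean, 3)
  expect_equal(b$metrics$completion_time$sd, sqrt(2))
  expect_equal(b$n_expert_segments, 2L)
  # invariant to novice rows
  b2 <- compute_baseline(ex)
  expect_equal(b$metrics, b2$metrics)
  expect_error(compute_baseline(nv), "no Expert segments")

  # single expert segment: sd 0, downstream z not available
  one <- compute_baseline(ex[1, ])
  expect_equal(one$metrics$completion_time$sd, 0)
  panel <- gauge_panel(nv, "S02", one)
  expect_true(all(is.na(panel$metrics$z_score)))
})

test_that("gauge z-scores measure distance from the expert mean in SD units", {
  ex <- gauge_ft(c(2, 2.5, 3, 3.5), 1, 0.3, 0.7, "S01", "Expert")
  b <- compute_baseline(ex)

  # surgeon identical to the experts scores zero everywhere
  self <- gauge_ft(c(2, 2.5, 3, 3.5), 1, 0.3, 0.7, "S03", "Novice")
  p0 <- gauge_panel(self, "S03", b)
  expect_true(all(abs(p0$metrics$z_score[p0$metrics$expert_sd > 0]) < 1e-9))

  # durations uniformly 1 s above an expert mean with sd 0.5 give z = 2
  ex2 <- gauge_ft(c(2.5, 3.5), 1, 0.3, 0.7, "S01", "Expert")  # sd ~0.707
  b2 <- compute_baseline(ex2)
  b2$metrics$completion_time$sd <- 0.5
  nv2 <- gauge_ft(c(4, 4), 1, 0.3, 0.7, "S04", "Novice")
  p2 <- gauge_panel(nv2, "S04", b2)
  expect_equal(p2$metrics$z_score[p2$metrics$metric == "completion_time"],
               2.0)
})

test_that("case-range selection changes the aggregation but never the baseline", {
  ex <- gauge_ft(c(2, 4), 1, 0.3, 0.7, "S01", "Expert")
  b <- compute_baseline(ex)
  nv <- gauge_ft(c(3, 9), c(1, 2), c(0.3, 0.5), c(0.7, 0.8), "S05",
                 "Novice", case_id = c("case_01", "case_02"))
  before <- unclass(b)
  p_all <- gauge_panel(nv, "S05", b)
  p_one <- gauge_panel(nv, "S05", b, case_range = "case_01")
  expect_equal(unclass(b), before)
  expect_equal(p_all$metrics$surgeon_value[1], 6)
  expect_equal(p_one$metrics$surgeon_value[1], 3)
  expect_identical(p_all$metrics$expert_mean, p_one$metrics$expert_mean)

  expect_error(gauge_panel(nv, "S05", b, case_range = "case_99"),
               "empty selection.*S05")
})

test_that("novice variability scores sit above the expert baseline on synthetic data", {
  zs <- vapply(1:3, function(r) {
    ds <- make_fixture("tiny", seed = 100 + r, n_per_cell = 8)
    ft <- extract_features(ds$table)
    b <- compute_baseline(ft)
    novices <- unique(ft$surgeon_id[ft$experience == "Novice"])
    mean(vapply(novices, function(s) {
      m <- gauge_panel(ft, s, b)$metrics
      m$z_score[m$metric == "variability_index"]
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(zs), 0)
})

test_that("gauge panels serialize to dashboard-ready JSON", {
  ex <- gauge_ft(c(2, 4), 1, 0.3, 0.7, "S01", "Expert")
  b <- compute_baseline(ex)
  p <- gauge_panel(ex, "S01", b)
  f <- withr::local_tempfile(fileext = ".json")
  write_gauge_panel(p, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$surgeon_id, "S01")
  expect_equal(nrow(back$metrics), 4L)
})
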