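test_that("recordings validate, infer sampling rate and round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,left_force_n,right_force_n",
               "0.00,0.1,0.1", "0.01,0.1,0.1", "0.02,0.1,0.1"), p)
  rec <- read_recording(p)
  expect_s3_class(rec, "force_recording")
  expect_equal(rec$sampling_rate, 100)

  # missing column -> format error
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,left_force_n", "0,1", "1,1"), p2)
  expect_error(read_recording(p2), "missing columns")

  # duplicated time values -> validation error
  expect_error(force_recording("c", c(0, 0.01, 0.01), 1:3, 1:3),
               "strictly increasing")
  expect_error(force_recording("c", c(0, 0.01, 0.02), c(1, NA, 3), 1:3),
               "finite")

  # 1000-sample round trip is bitwise exact
  set.seed(1)
  tt <- seq(0, 9.99, by = 0.01)
  rec2 <- force_recording("rt", tt, rnorm(1000), rnorm(1000))
  p3 <- withr::local_tempfile(fileext = ".csv")
  # write with full precision
  df <- data.frame(time_s = sprintf("%.17g", rec2$time),
                   left_force_n = sprintf("%.17g", rec2$left_force),
                   right_force_n = sprintf("%.17g", rec2$right_force))
  write.csv(df, p3, row.names = FALSE, quote = FALSE)
  back <- read_recording(p3)
  expect_identical(back$left_force, rec2$left_force)
  expect_identical(back$right_force, rec2$right_force)
})

test_that("segmentation follows the half-open interval rule", {
  tt <- seq(0, 9.99, by = 0.01)
  rec <- force_recording("c1", tt, sin(tt), cos(tt))
  ann <- segment_annotation(2.0, 4.0, "Pulling", "S01", "Expert")
  tab <- segment_recording(rec, ann)
  expect_equal(length(tab), 1L)
  expect_equal(length(tab$segments[[1]]$right_force), 200L)
  expect_equal(tab$segments[[1]]$duration, 2.0)

  # annotation fully outside the recording: dropped with a warning
  ann2 <- segment_annotation(50, 60, "Pulling", "S01", "Expert")
  expect_warning(tab2 <- segment_recording(rec, ann2), "dropped")
  expect_equal(length(tab2), 0L)

  # clock offset shifts the window by exactly offset * fs samples
  ann3 <- segment_annotation(2.0, 4.0, "Pulling", "S01", "Expert")
  tab3 <- segment_recording(rec, ann3, clock_offset = 0.5)
  ref <- rec$right_force[which(rec$time >= 2.5 & rec$time < 4.5)]
  expect_equal(tab3$segments[[1]]$right_force, ref)
  idx0 <- which(rec$time >= 2.0 & rec$time < 4.0)
  expect_equal(tab3$segments[[1]]$right_force, rec$right_force[idx0 + 50L])

  # overlap is rejected
  ann4 <- segment_annotation(c(1, 2.5), c(3, 4), c("Pulling", "Dissecting"),
                             "S01", "Expert")
  expect_error(segment_recording(rec, ann4), "overlap")

  # tiling annotations partition the recording exactly
  ann5 <- segment_annotation(c(0, 2, 5), c(2, 5, 10),
                             c("Pulling", "Dissecting", "Coagulation"),
                             "S01", "Expert")
  tab5 <- segment_recording(rec, ann5)
  expect_equal(sum(vapply(tab5$segments, function(s)
    length(s$right_force), 1L)), length(rec$time))
})

test_that("task and experience labels form closed sets", {
  expect_error(segment_annotation(0, 1, "Suturing", "S01", "Expert"),
               "unknown task")
  expect_error(segment_annotation(0, 1, "Pulling", "S01", "Intermediate"),
               "Expert or Novice")
  expect_error(segment_annotation(1, 1, "Pulling", "S01", "Expert"),
               "start must be")
  expect_error(segment_annotation(0, 1, "Pulling", "S01", "Expert",
                                  event_flags = list("exploded")),
               "unknown event flag")
})

test_that("segment tables round-trip through CSV + JSON sidecar", {
  ds <- make_fixture("tiny", seed = 4, n_per_cell = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_segments(ds$table, p)
  back <- read_segments(p)
  expect_equal(length(back), length(ds$table))
  for (i in seq_along(back$segments)) {
    a <- ds$table$segments[[i]]
    b <- back$segments[[i]]
    expect_equal(b$right_force, a$right_force, tolerance = 1e-12)
    expect_identical(b$task, a$task)
    expect_identical(b$experience, a$experience)
    expect_identical(b$surgeon_id, a$surgeon_id)
    expect_equal(b$sampling_rate, a$sampling_rate)
  }

  # empty table: header-only CSV, empty metadata list
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_segments(segment_table(list()), p2)
  expect_equal(nrow(read.csv(p2)), 0L)
  expect_length(jsonlite::read_json(paste0(p2, ".meta.json"))$segments, 0L)

  # sidecar missing a segment -> format error
  side <- jsonlite::read_json(paste0(p, ".meta.json"))
  side$segments <- side$segments[-1]
  jsonlite::write_json(side, paste0(p, ".meta.json"), auto_unbox = TRUE)
  expect_error(read_segments(p), "mismatch")
})

test_that("duplicate segment ids are rejected", {
  s <- seg_of(c(1, 2, 3))
  expect_error(segment_table(list(s, s)), "unique")
})
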