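# lightweight training profile for unit tests; the full-scale behaviour
# is exercised in the acceptance suite
tiny_task_cfg <- function(seed = 9, ...) {
  task_config(input_length = 32, lstm_units = 16, dense_units = 16,
              epochs = 40, batch_size = 10, n_repeats = 2, seed = seed, ...)
}

test_that("resampling maps segments onto standardized fixed-length vectors", {
  expect_equal(resample_segment(seg_of(rep(2, 50)), 100), rep(0, 100))

  x <- seq(0, 1, length.out = 100)
  v <- resample_segment(seg_of(x), 100)
  expect_equal(v, (x - mean(x)) / sd(x), tolerance = 1e-10)

  # a 57-sample ramp interpolates exactly onto the new grid
  ramp <- seq(3, 10, length.out = 57)
  v2 <- resample_segment(seg_of(ramp), 100)
  grid <- seq(1, 57, length.out = 100)
  ref <- 3 + (grid - 1) / 56 * 7
  ref <- (ref - mean(ref)) / sd(ref)
  expect_equal(v2, ref, tolerance = 1e-10)
  expect_equal(v2[1], ref[1])
  expect_equal(v2[100], ref[100])

  expect_error(resample_segment(seg_of(1), 100), "too short")
})

test_that("the recogniser learns distinct task motifs and reports per-repeat metrics", {
  ds <- make_fixture("tiny", seed = 3, n_per_cell = 12)
  fit <- train_task_model(ds$table, tiny_task_cfg())
  r <- fit$result
  expect_length(r$per_repeat, 2L)
  expect_gte(r$mean_accuracy, 0.8)
  expect_true(r$mean_mse >= 0 && r$mean_mse <= 1)
  expect_equal(r$sd_accuracy,
               sd(vapply(r$per_repeat, `[[`, 0, "accuracy")))
})

test_that("training is reproducible given the seed", {
  ds <- make_fixture("tiny", seed = 5, n_per_cell = 6)
  cfg <- tiny_task_cfg(seed = 17)
  f1 <- train_task_model(ds$table, cfg)
  f2 <- train_task_model(ds$table, cfg)
  for (r in 1:2) {
    expect_equal(f1$result$per_repeat[[r]]$loss,
                 f2$result$per_repeat[[r]]$loss, tolerance = 1e-6)
    expect_equal(f1$result$per_repeat[[r]]$accuracy,
                 f2$result$per_repeat[[r]]$accuracy)
  }
})

test_that("label shuffling keeps evaluation accuracy near 5-class chance", {
  ds <- make_fixture("tiny", seed = 7, n_per_cell = 12)
  segs <- ds$table$segments
  set.seed(99)
  tasks <- sample(vapply(segs, `[[`, "", "task"))
  shuffled <- segment_table(lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    s$task <- tasks[i]
    s
  }))
  fit <- train_task_model(shuffled, tiny_task_cfg(seed = 23))
  expect_gte(fit$result$mean_accuracy, 0.1)
  expect_lte(fit$result$mean_accuracy, 0.35)
})

test_that("predictions are valid probability rows and deterministic", {
  ds <- make_fixture("tiny", seed = 11, n_per_cell = 6)
  fit <- train_task_model(ds$table, tiny_task_cfg(seed = 31))
  pr <- predict_task(fit, ds$table)
  pcols <- paste0("p_", TASK_LEVELS)
  expect_true(all(abs(rowSums(pr[, pcols]) - 1) < 1e-6))
  expect_identical(pr$task,
                   TASK_LEVELS[max.col(as.matrix(pr[, pcols]))])

  # duplicated segment gives an identical prediction row
  s2 <- ds$table$segments[[1]]
  s2$segment_id <- "copy"
  dup <- segment_table(list(ds$table$segments[[1]], s2))
  prd <- predict_task(fit, dup)
  expect_equal(unlist(prd[1, pcols]), unlist(prd[2, pcols]))

  # on the separable synthetic set the confusion matrix is
  # diagonally dominant
  truth <- vapply(ds$table$segments, `[[`, "", "task")
  cm <- table(truth, pr$task)
  for (lv in intersect(rownames(cm), colnames(cm)))
    expect_gte(cm[lv, lv], sum(cm[lv, ]) - cm[lv, lv])
})

test_that("untrained networks sit at chance and config errors are caught", {
  ds <- make_fixture("tiny", seed = 13, n_per_cell = 20)
  cfg <- tiny_task_cfg(seed = 41)
  cfg$epochs <- 0L
  # a single untrained network maps the 5 motif shapes to arbitrary
  # classes, so chance behaviour only emerges on average over inits
  cfg$n_repeats <- 10L
  fit <- train_task_model(ds$table, cfg)
  expect_gte(fit$result$mean_accuracy, 0.1)
  expect_lte(fit$result$mean_accuracy, 0.35)

  # a missing class is a configuration error
  part <- segment_table(Filter(function(s) s$task != "Pulling",
                               ds$table$segments))
  expect_error(train_task_model(part, cfg), "configuration error")
  expect_error(task_config(input_length = 4), "at least 8")
  expect_error(task_config(dropout_rate = 1), "dropout_rate")
})

test_that("fitted task models round-trip through the JSON save format", {
  ds <- make_fixture("tiny", seed = 15, n_per_cell = 6)
  fit <- train_task_model(ds$table, tiny_task_cfg(seed = 51))
  p <- withr::local_tempfile(fileext = ".json")
  save_task_model(fit, p)
  back <- load_task_model(p)
  pr1 <- predict_task(fit, ds$table)
  pr2 <- predict_task(back, ds$table)
  expect_equal(pr2[, -1], pr1[, -1], tolerance = 1e-9)
})
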