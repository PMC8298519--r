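#' Task model configuration
#'
#' Architecture and training settings for the five-class surgical task
#' recogniser: a fixed-length input layer fed by resampled force signals,
#' one hidden layer of LSTM units, a dropout layer, a ReLU dense layer and
#' a softmax output, trained with Adam on categorical cross-entropy. The
#' canonical architecture is 100 inputs, 100 LSTM units, dropout 0.5 and
#' 100 dense units. The default training profile here runs 200 epochs,
#' which is sufficient on desk-scale synthetic data; the 1000-epoch
#' setting used for the original clinical experiments is reachable via
#' `epochs`.
#'
#' @param input_length Resampled input length (samples), >= 8. Default 100.
#' @param lstm_units Hidden LSTM units. Default 100.
#' @param dropout_rate Dropout fraction on the LSTM output, in `[0, 1)`.
#'   Default 0.5.
#' @param dense_units Units of the ReLU dense layer. Default 100.
#' @param epochs Training epochs per repeat. Default 200.
#' @param batch_size Minibatch size. Default 20.
#' @param n_repeats Independent training repeats (different derived
#'   seeds); metrics are reported as mean (SD) over repeats. Default 4.
#' @param learning_rate Adam step size. Default 0.001.
#' @param test_fraction Held-out stratified evaluation fraction. Default
#'   0.30.
#' @param channel Analysis channel resampled into the input vector.
#' @param seed Integer seed for the split and the derived per-repeat
#'   training seeds.
#' @return An object of class `task_config`. The class count is fixed at
#'   5 (the closed task label set).
#' @export
task_config <- function(input_length = 100L, lstm_units = 100L,
                        dropout_rate = 0.5, dense_units = 100L,
                        epochs = 200L, batch_size = 20L, n_repeats = 4L,
                        learning_rate = 0.001, test_fraction = 0.30,
                        channel = "right", seed = 1L) {
  if (input_length < 8L)
    stop("parameter error: input_length must be at least 8")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("parameter error: dropout_rate must be in [0, 1)")
  structure(list(input_length = as.integer(input_length),
                 lstm_units = as.integer(lstm_units),
                 dropout_rate = dropout_rate,
                 dense_units = as.integer(dense_units),
                 n_classes = 5L, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_repeats = as.integer(n_repeats),
                 learning_rate = learning_rate,
                 test_fraction = test_fraction, channel = channel,
                 seed = as.integer(seed)),
            class = "task_config")
}

#' Resample a segment to a fixed-length standardized vector
#'
#' The analysis channel is linearly interpolated onto `input_length`
#' equally spaced points spanning the segment, then standardized to zero
#' mean and unit (sample) variance; a zero-variance segment maps to the
#' zero vector. This isolates the variable-length-to-fixed-input rule so
#' alternatives (padding, truncation) can be substituted.
#'
#' @param seg A [force_segment()] with at least 2 samples.
#' @param input_length Output length. Default 100.
#' @param channel Analysis channel.
#' @return Numeric vector of length `input_length`.
#' @export
resample_segment <- function(seg, input_length = 100L, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  if (n < 2L)
    stop("segment too short to resample: need at least 2 samples")
  y <- approx(x = seq_len(n), y = x, n = input_length)$y
  s <- sd(y)
  if (!is.finite(s) || s == 0) return(rep(0, input_length))
  (y - mean(y)) / s
}

segments_to_matrix <- function(table, input_length, channel) {
  t(vapply(table$segments, resample_segment, numeric(input_length),
           input_length = input_length, channel = channel))
}

#' Train the five-class task recogniser
#'
#' Builds the fixed-length input matrix via [resample_segment()], holds
#' out a seeded stratified evaluation split, and trains the LSTM network
#' `config$n_repeats` times with derived seeds. Held-out metrics per
#' repeat are categorical cross-entropy loss, accuracy and the mean
#' squared error between one-hot labels and softmax outputs; the result
#' carries their mean and SD over repeats. All reported metrics are
#' held-out values.
#'
#' @param table A [segment_table()] containing all five task labels with
#'   at least 2 segments each.
#' @param config A [task_config()].
#' @return An object of class `task_model` with elements `result` (class
#'   `task_result`: `per_repeat`, `mean_loss`, `sd_loss`,
#'   `mean_accuracy`, `sd_accuracy`, `mean_mse`, `sd_mse`, `seed`),
#'   `weights` (of the final repeat, used by [predict_task()]) and the
#'   split bookkeeping.
#' @export
train_task_model <- function(table, config = task_config()) {
  stopifnot(inherits(table, "segment_table"), inherits(config, "task_config"))
  tasks <- vapply(table$segments, `[[`, "", "task")
  y <- factor(tasks, levels = TASK_LEVELS)
  counts <- table(y)
  if (any(counts < 2L))
    stop("configuration error: all 5 task classes need at least 2 segments; missing or sparse: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  X <- segments_to_matrix(table, config$input_length, config$channel)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  test_idx <- sort(stratified_test_idx(y, config$test_fraction))
  train_idx <- setdiff(seq_along(y), test_idx)

  ytr <- as.integer(y[train_idx]) - 1L
  yte <- as.integer(y[test_idx]) - 1L
  onehot <- diag(config$n_classes)[yte + 1L, , drop = FALSE]
  per_repeat <- vector("list", config$n_repeats)
  weights <- NULL
  for (r in seq_len(config$n_repeats)) {
    rep_seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    weights <- .lstm_train(X[train_idx, , drop = FALSE], ytr,
                           config$n_classes, config$lstm_units,
                           config$dense_units, config$dropout_rate,
                           config$epochs, config$batch_size,
                           config$learning_rate, rep_seed)
    probs <- .lstm_predict(weights, X[test_idx, , drop = FALSE])
    eps <- 1e-12
    loss <- -mean(log(pmax(probs[cbind(seq_along(yte), yte + 1L)], eps)))
    acc <- mean(max.col(probs) == yte + 1L)
    mse <- mean((probs - onehot)^2)
    per_repeat[[r]] <- list(loss = loss, accuracy = acc, mse = mse,
                            seed = rep_seed)
  }
  losses <- vapply(per_repeat, `[[`, 0, "loss")
  accs <- vapply(per_repeat, `[[`, 0, "accuracy")
  mses <- vapply(per_repeat, `[[`, 0, "mse")
  result <- structure(list(
    per_repeat = per_repeat,
    mean_loss = mean(losses), sd_loss = sd(losses),
    mean_accuracy = mean(accs), sd_accuracy = sd(accs),
    mean_mse = mean(mses), sd_mse = sd(mses),
    seed = config$seed), class = "task_result")
  structure(list(result = result, weights = weights, config = config,
                 classes = TASK_LEVELS, test_idx = test_idx),
            class = "task_model")
}

#' @export
print.task_model <- function(x, ...) {
  r <- x$result
  cat(sprintf(paste0("<task_model> LSTM(%d) x dense(%d), dropout %.2f, ",
                     "%d epochs x %d repeats\n",
                     "  held-out loss %.3f (%.3f) | accuracy %.3f (%.3f)",
                     " | mse %.4f (%.4f)\n"),
              x$config$lstm_units, x$config$dense_units,
              x$config$dropout_rate, x$config$epochs, x$config$n_repeats,
              r$mean_loss, if (is.na(r$sd_loss)) 0 else r$sd_loss,
              r$mean_accuracy,
              if (is.na(r$sd_accuracy)) 0 else r$sd_accuracy,
              r$mean_mse, if (is.na(r$sd_mse)) 0 else r$sd_mse))
  invisible(x)
}

#' Predict task labels for segments
#'
#' @param model A [train_task_model()] fit.
#' @param table A [segment_table()] (segments are resampled with the
#'   model's input length and channel).
#' @return Data frame with `segment_id`, `task` (argmax label) and five
#'   probability columns `p_<task>`; probabilities sum to 1 per row.
#' @export
predict_task <- function(model, table) {
  stopifnot(inherits(model, "task_model"), inherits(table, "segment_table"))
  X <- segments_to_matrix(table, model$config$input_length,
                          model$config$channel)
  if (ncol(X) != model$config$input_length)
    stop("schema error: input length mismatch")
  probs <- .lstm_predict(model$weights, X)
  colnames(probs) <- paste0("p_", model$classes)
  out <- data.frame(segment_id = vapply(table$segments, `[[`, "",
                                        "segment_id"),
                    task = model$classes[max.col(probs)],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' Save / load a fitted task model
#'
#' Weights and configuration are serialized as JSON (text), so fitted
#' models survive text-only archival.
#'
#' @param model A [train_task_model()] fit.
#' @param path JSON output path.
#' @return `path` invisibly, or the restored `task_model`.
#' @export
save_task_model <- function(model, path) {
  stopifnot(inherits(model, "task_model"))
  payload <- list(weights = lapply(model$weights, unclass),
                  config = unclass(model$config),
                  classes = model$classes,
                  result = unclass(model$result))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_task_model
#' @export
load_task_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- p$weights
  for (nm in c("Wx", "Wh", "Wd", "Wo"))
    w[[nm]] <- as.matrix(w[[nm]])
  for (nm in c("b", "bd", "bo", "train_loss"))
    w[[nm]] <- as.numeric(w[[nm]])
  cfg <- p$config
  class(cfg) <- "task_config"
  structure(list(result = p$result, weights = w, config = cfg,
                 classes = p$classes, test_idx = integer(0)),
            class = "task_model")
}

#' Write a task model result as JSON
#' @param model A [train_task_model()] fit.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_task_result <- function(model, path) {
  stopifnot(inherits(model, "task_model"))
  jsonlite::write_json(unclass(model$result), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
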