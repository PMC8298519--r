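#' Skill model configuration
#'
#' Settings for the expert-versus-novice classifier: standardization and
#' PCA fitted on the training split only, followed by a radial-basis SVM
#' whose cost and gamma are grid-searched by cross-validated training
#' accuracy. The default grids include `0.1 * 10^0.1` (~0.12589), the
#' optimum reported for the original clinical experiments.
#'
#' @param feature_subset Feature names used as predictors. Default: the
#'   25-feature modelling subset.
#' @param pca_variance_retained Fraction of training variance the retained
#'   principal components must explain. Default 0.95.
#' @param cost_grid,gamma_grid Positive candidate values for the SVM cost
#'   and RBF gamma.
#' @param test_fraction Held-out fraction for the stratified test split.
#'   Default 0.30.
#' @param cv_folds Cross-validation folds for the grid search. Default 5.
#' @param class_weights Optional named weights (`Expert`, `Novice`) for
#'   unbalanced data; `NULL` (default) leaves classes unweighted.
#' @param seed Integer seed controlling the split, fold assignment and SVM
#'   fitting.
#' @return An object of class `skill_config`.
#' @export
skill_config <- function(feature_subset = select_model_subset(mode = "fixed"),
                         pca_variance_retained = 0.95,
                         cost_grid = c(0.1 * 10^0.1, 1, 10),
                         gamma_grid = c(0.01, 0.1 * 10^0.1, 1),
                         test_fraction = 0.30, cv_folds = 5,
                         class_weights = NULL, seed = 1L) {
  if (!length(cost_grid) || !length(gamma_grid))
    stop("parameter error: cost_grid and gamma_grid must be non-empty")
  if (any(cost_grid <= 0) || any(gamma_grid <= 0))
    stop("parameter error: grid entries must be positive")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("parameter error: test_fraction must be in (0, 1)")
  structure(list(feature_subset = feature_subset,
                 pca_variance_retained = pca_variance_retained,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds),
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "skill_config")
}

# stratified index split: returns indices of the test set
stratified_test_idx <- function(y, fraction) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    n_test <- max(1L, round(length(idx) * fraction))
    sample(idx, n_test)
  }), use.names = FALSE)
}

#' Train the expert-versus-novice skill classifier
#'
#' Pipeline: median imputation of missing feature values (medians from the
#' training split), standardization and PCA fitted on the training split
#' only, then an RBF-kernel SVM grid-searched over (cost, gamma) by
#' cross-validated accuracy on the training split. Sensitivity is the
#' recall of the Expert class, specificity the recall of the Novice class;
#' AUC is computed from decision scores on the held-out test split. The
#' whole procedure is reproducible given `config$seed`.
#'
#' @param features A [extract_features()] table with both experience
#'   classes present (each with at least `cv_folds` segments).
#' @param config A [skill_config()].
#' @return An object of class `skill_model` with a `result` element
#'   (`auc`, `train_accuracy`, `test_accuracy`, `sensitivity`,
#'   `specificity`, `best_cost`, `best_gamma`, `n_components_used`,
#'   `seed`) and the fitted transform (imputation medians, scaling, PCA
#'   rotation, SVM).
#' @export
train_skill_model <- function(features, config = skill_config()) {
  stopifnot(inherits(features, "feature_table"),
            inherits(config, "skill_config"))
  y <- factor(features$experience, levels = EXPERIENCE_LEVELS)
  if (nlevels(droplevels(y)) < 2L)
    stop("configuration error: both Expert and Novice segments are required")
  if (any(table(y) < config$cv_folds))
    stop("configuration error: each class needs at least cv_folds segments")
  miss <- setdiff(config$feature_subset, names(features))
  if (length(miss))
    stop("schema error: missing feature columns: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(features[, config$feature_subset, drop = FALSE])

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)

  test_idx <- sort(stratified_test_idx(y, config$test_fraction))
  train_idx <- setdiff(seq_along(y), test_idx)

  # median imputation, medians from the training split only
  med <- apply(X[train_idx, , drop = FALSE], 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- med[j]

  ctr <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  pca <- stats::prcomp(Xs[train_idx, , drop = FALSE], center = FALSE,
                       scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  ncomp <- which(cum >= config$pca_variance_retained)[1]
  if (is.na(ncomp)) ncomp <- length(pca$sdev)
  Z <- Xs %*% pca$rotation[, seq_len(ncomp), drop = FALSE]

  ytr <- droplevels(y[train_idx])
  Ztr <- Z[train_idx, , drop = FALSE]
  folds <- make_cv_folds(ytr, config$cv_folds)
  grid <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid)
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(config$cv_folds), function(k) {
      tr <- folds != k
      fit <- e1071::svm(Ztr[tr, , drop = FALSE], ytr[tr],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE,
                        class.weights = config$class_weights)
      mean(predict(fit, Ztr[!tr, , drop = FALSE]) == ytr[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(cv_acc)

  fit <- e1071::svm(Ztr, ytr, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE,
                    class.weights = config$class_weights,
                    decision.values = TRUE)

  score_of <- function(Zm) {
    dv <- attr(predict(fit, Zm, decision.values = TRUE),
               "decision.values")
    # orient so that larger score means more Expert-like
    pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
    if (pair[1] == "Expert") drop(dv) else -drop(dv)
  }
  pred_tr <- predict(fit, Ztr)
  yte <- y[test_idx]
  Zte <- Z[test_idx, , drop = FALSE]
  pred_te <- predict(fit, Zte)
  score_te <- score_of(Zte)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = yte, predictor = score_te,
    levels = c("Novice", "Expert"), direction = "<", quiet = TRUE)))
  result <- list(
    auc = auc,
    train_accuracy = mean(pred_tr == ytr),
    test_accuracy = mean(pred_te == yte),
    sensitivity = mean(pred_te[yte == "Expert"] == "Expert"),
    specificity = mean(pred_te[yte == "Novice"] == "Novice"),
    best_cost = grid$cost[best],
    best_gamma = grid$gamma[best],
    n_components_used = ncomp,
    seed = config$seed)
  structure(list(result = result, svm = fit, rotation = pca$rotation,
                 n_components = ncomp, center = ctr, scale = scl,
                 medians = med, feature_subset = config$feature_subset,
                 test_idx = test_idx, config = config),
            class = "skill_model")
}

make_cv_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' @export
print.skill_model <- function(x, ...) {
  r <- x$result
  cat(sprintf(paste0("<skill_model> RBF-SVM on %d principal components\n",
                     "  AUC %.3f | train acc %.3f | test acc %.3f | ",
                     "sens %.3f | spec %.3f\n",
                     "  best cost %.5g, best gamma %.5g (seed %d)\n"),
              r$n_components_used, r$auc, r$train_accuracy,
              r$test_accuracy, r$sensitivity, r$specificity,
              r$best_cost, r$best_gamma, r$seed))
  invisible(x)
}

#' Predict skill class for segments
#'
#' Applies the fitted imputation/standardization/PCA transform and SVM to
#' a feature table.
#'
#' @param model A [train_skill_model()] fit.
#' @param features A [extract_features()] table containing the model's
#'   feature columns.
#' @return Data frame with `segment_id`, `class` and `score` (larger =
#'   more Expert-like, monotone in class probability).
#' @export
predict_skill <- function(model, features) {
  stopifnot(inherits(model, "skill_model"))
  miss <- setdiff(model$feature_subset, names(features))
  if (length(miss))
    stop("schema error: missing feature columns: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(features[, model$feature_subset, drop = FALSE])
  for (j in seq_len(ncol(X)))
    X[!is.finite(X[, j]), j] <- model$medians[j]
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Z <- Xs %*% model$rotation[, seq_len(model$n_components), drop = FALSE]
  pred <- predict(model$svm, Z, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  score <- if (pair[1] == "Expert") drop(dv) else -drop(dv)
  data.frame(segment_id = features$segment_id,
             class = as.character(pred), score = unname(score),
             stringsAsFactors = FALSE)
}

#' Write a skill model result as JSON
#' @param model A [train_skill_model()] fit.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_skill_result <- function(model, path) {
  stopifnot(inherits(model, "skill_model"))
  jsonlite::write_json(model$result, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# save/restore the global RNG state so seeded model fits do not disturb
# the caller's random stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
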