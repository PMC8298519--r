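# shared fixture builders

# wrap a numeric vector as a one-channel force segment (both prongs equal)
seg_of <- function(x, fs = 1, task = "Coagulation", experience = "Expert",
                   id = "seg1", surgeon = "S01", case_id = "case_01") {
  force_segment(segment_id = id, case_id = case_id, sampling_rate = fs,
                left_force = x, right_force = x, task = task,
                surgeon_id = surgeon, experience = experience)
}

# segment table of independent one-channel segments
table_of <- function(xs, fs = 1, tasks = "Coagulation",
                     experiences = "Expert", surgeons = "S01") {
  n <- length(xs)
  tasks <- rep_len(tasks, n)
  experiences <- rep_len(experiences, n)
  surgeons <- rep_len(surgeons, n)
  segment_table(lapply(seq_len(n), function(i)
    seg_of(xs[[i]], fs = fs, task = tasks[i], experience = experiences[i],
           id = sprintf("seg%04d", i), surgeon = surgeons[i])))
}

# two Gaussian clouds in the 25-feature modelling space, Expert vs Novice
make_gaussian_features <- function(n_per_class, separation, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subset <- select_model_subset(mode = "fixed")
  n <- n_per_class
  X <- rbind(matrix(rnorm(n * length(subset)), n),
             matrix(rnorm(n * length(subset), mean = separation), n))
  df <- as.data.frame(X)
  names(df) <- subset
  df <- cbind(data.frame(
    segment_id = sprintf("s%05d", seq_len(2 * n)),
    case_id = rep(sprintf("case_%02d", 1:5), length.out = 2 * n),
    task = rep(TASK_LEVELS, length.out = 2 * n),
    surgeon_id = rep(c("S01", "S02"), each = n),
    experience = rep(c("Expert", "Novice"), each = n),
    stringsAsFactors = FALSE), df)
  for (f in setdiff(FEATURE_CATALOGUE, subset)) df[[f]] <- rnorm(2 * n)
  class(df) <- c("feature_table", "data.frame")
  df
}

# ---- independent brute-force oracles -------------------------------------

# flat spots by explicit run enumeration over ten equal-width bins
oracle_flat_spots <- function(x) {
  if (max(x) == min(x)) return(length(x))
  breaks <- seq(min(x), max(x), length.out = 11)
  bin <- function(v) {
    b <- 10
    for (j in 1:10) if (v <= breaks[j + 1]) { b <- j; break }
    b
  }
  bins <- vapply(x, bin, 1)
  best <- 1; run <- 1
  for (i in 2:length(x)) {
    run <- if (bins[i] == bins[i - 1]) run + 1 else 1
    best <- max(best, run)
  }
  best
}

# spikiness by the literal double loop over leave-one-out variances
oracle_spikiness <- function(rem) {
  v <- numeric(length(rem))
  for (i in seq_along(rem)) v[i] <- var(rem[-i])
  var(v)
}

# sliding adjacent-window shifts by direct evaluation at every offset
oracle_window_shifts <- function(x, w, var_floor = 1e-8) {
  n <- length(x)
  ms <- vs <- kl <- -Inf
  for (s in 1:(n - 2 * w + 1)) {
    w1 <- x[s:(s + w - 1)]
    w2 <- x[(s + w):(s + 2 * w - 1)]
    m1 <- mean(w1); m2 <- mean(w2)
    v1 <- max(var(w1), var_floor); v2 <- max(var(w2), var_floor)
    ms <- max(ms, abs(m2 - m1))
    vs <- max(vs, abs(v2 - v1))
    kl <- max(kl, 0.5 * (log(v2 / v1) + (v1 + (m1 - m2)^2) / v2 - 1))
  }
  list(max_mean_shift = ms, max_var_shift = vs, max_kl_shift = kl)
}

# KPSS trend statistic assembled step by step from its definition
oracle_kpss <- function(x) {
  n <- length(x)
  tt <- 1:n
  fit <- lm(x ~ tt)
  e <- x - fitted(fit)
  S <- cumsum(e)
  g0 <- sum(e^2) / n
  g1 <- sum(e[2:n] * e[1:(n - 1)]) / n
  lrv <- g0 + 2 * (1 - 1 / 2) * g1
  sum(S^2) / (n^2 * lrv)
}

# peak count by testing every interior sample against the prominence
# definition directly
oracle_peak_count <- function(x, frac = 0.05) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng == 0 || n < 3) return(0)
  count <- 0
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] > x[i + 1])) next
    lo <- i - 1
    while (lo >= 1 && x[lo] <= x[i]) lo <- lo - 1
    left_min <- min(x[(lo + 1):(i - 1)])
    hi <- i + 1
    while (hi <= n && x[hi] <= x[i]) hi <- hi + 1
    right_min <- min(x[(i + 1):(hi - 1)])
    if (x[i] - max(left_min, right_min) >= frac * rng) count <- count + 1
  }
  count
}
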