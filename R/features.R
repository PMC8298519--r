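#' The fixed 37-feature catalogue
#'
#' Names, in canonical order, of the hand-crafted time-series features
#' computed per force segment. Units: seconds for `duration`,
#' `cycle_length` and the autocorrelation timing features; Newtons for
#' force moments, peaks and shift magnitudes; `d1_sd` in Newtons/second;
#' dimensionless otherwise.
#'
#' @export
FEATURE_CATALOGUE <- c(
  "duration", "mean", "max", "min", "range", "median", "sd", "cv",
  "mean_ci95_halfwidth", "skewness", "skewness_2se", "kurtosis",
  "kurtosis_2se", "shapiro_w", "shapiro_p", "peak_value", "peak_count",
  "d1_sd", "flat_spots", "dominant_freq", "cycle_length", "trend",
  "fluctuation", "spikiness", "linearity", "stability", "lumpiness",
  "curvature", "max_mean_shift", "max_var_shift", "max_kl_shift",
  "kpss_stat", "spectral_entropy", "acf_first_min_time",
  "acf_first_zero_time", "acf_e1", "acf_e10")

#' Feature engine configuration
#'
#' @param channel Analysis channel (`"right"`, `"left"` or `"max"`): the
#'   canonical feature vector is computed on a single designated prong.
#' @param window_width Window width in samples for the tiled/sliding
#'   window statistics (stability, lumpiness, shifts). Default 10.
#' @param prominence_fraction Peak prominence threshold as a fraction of
#'   the segment's force range. Default 0.05.
#' @param loess_span Span of the local regression used to estimate the
#'   smooth trend component. Default 0.75.
#' @param acf_lag_max Cap on the number of autocorrelation lags examined
#'   for the timing features. Default 100.
#' @param var_floor Lower floor for window variances inside the
#'   Kullback-Leibler shift statistic. Default 1e-8.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(channel = "right", window_width = 10L,
                           prominence_fraction = 0.05, loess_span = 0.75,
                           acf_lag_max = 100L, var_floor = 1e-8) {
  stopifnot(window_width >= 2, prominence_fraction >= 0, loess_span > 0,
            acf_lag_max >= 10, var_floor > 0)
  structure(list(channel = channel, window_width = as.integer(window_width),
                 prominence_fraction = prominence_fraction,
                 loess_span = loess_span,
                 acf_lag_max = as.integer(acf_lag_max),
                 var_floor = var_floor),
            class = "feature_config")
}

#' Basic moment statistics of a segment
#'
#' @param seg A [force_segment()] with at least 2 samples.
#' @param channel Analysis channel.
#' @return Named list: `duration` (s), `mean`, `max`, `min`, `range`,
#'   `median`, `sd` (sample, n-1), `cv` (`sd/mean`, `NA` when the mean is
#'   0) and `mean_ci95_halfwidth` (`t(0.975, n-1) * sd / sqrt(n)`), forces
#'   in Newtons.
#' @export
basic_stats <- function(seg, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  if (n < 2L)
    return(list(duration = seg$duration, mean = mean(x), max = max(x),
                min = min(x), range = 0, median = median(x), sd = NA_real_,
                cv = NA_real_, mean_ci95_halfwidth = NA_real_))
  m <- mean(x)
  s <- sd(x)
  list(duration = seg$duration, mean = m, max = max(x), min = min(x),
       range = max(x) - min(x), median = median(x), sd = s,
       cv = if (m == 0) NA_real_ else s / m,
       mean_ci95_halfwidth = qt(0.975, n - 1) * s / sqrt(n))
}

# adjusted (sample) skewness G1 and excess kurtosis G2 with their
# standard errors; the *_2se entries are the statistic divided by twice
# its standard error, read as significant when |value| > 1
#' Distribution-shape statistics of a segment
#'
#' @param seg A [force_segment()].
#' @param channel Analysis channel.
#' @return Named list: `skewness` (adjusted sample skewness), `skewness_2se`,
#'   `kurtosis` (sample excess kurtosis), `kurtosis_2se`, `shapiro_w` and
#'   `shapiro_p` (Shapiro-Wilk normality test, defined for 3 <= n <= 5000).
#'   Entries outside their n-range are `NA`.
#' @export
distribution_stats <- function(seg, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  out <- list(skewness = NA_real_, skewness_2se = NA_real_,
              kurtosis = NA_real_, kurtosis_2se = NA_real_,
              shapiro_w = NA_real_, shapiro_p = NA_real_)
  if (n >= 3L && sd(x) > 0) {
    g1 <- e1071::skewness(x, type = 2)
    se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
    out$skewness <- g1
    out$skewness_2se <- g1 / (2 * se_skew)
    if (n >= 4L) {
      g2 <- e1071::kurtosis(x, type = 2)
      se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
      out$kurtosis <- g2
      out$kurtosis_2se <- g2 / (2 * se_kurt)
    }
    if (n >= 3L && n <= 5000L) {
      sw <- tryCatch(shapiro.test(x), error = function(e) NULL)
      if (!is.null(sw)) {
        out$shapiro_w <- unname(sw$statistic)
        out$shapiro_p <- sw$p.value
      }
    }
  }
  out
}

# local maxima with topographic prominence >= min_prom; plateau-free
# strict definition (a peak is strictly above both neighbours)
find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    h <- x[i]
    # walk left to the previous strictly higher sample (or the edge)
    l <- i - 1L
    lmin <- x[l]
    while (l >= 1L && x[l] <= h) {
      if (x[l] < lmin) lmin <- x[l]
      l <- l - 1L
    }
    r <- i + 1L
    rmin <- x[r]
    while (r <= n && x[r] <= h) {
      if (x[r] < rmin) rmin <- x[r]
      r <- r + 1L
    }
    keep[j] <- (h - max(lmin, rmin)) >= min_prom
  }
  cand[keep]
}

#' Peak-related statistics of a segment
#'
#' Peaks are local maxima whose topographic prominence is at least
#' `prominence_fraction` of the segment's force range.
#'
#' @param seg A [force_segment()] with at least 3 samples.
#' @param prominence_fraction Prominence threshold as a fraction of range.
#' @param channel Analysis channel.
#' @return Named list: `peak_value` (global maximum, N), `peak_count`,
#'   `cycle_length` (mean inter-peak interval in seconds; `NA` with fewer
#'   than 2 peaks) and `d1_sd` (sample SD of the first difference divided
#'   by the sample period, N/s).
#' @export
peak_stats <- function(seg, prominence_fraction = 0.05, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  fs <- seg$sampling_rate
  if (n < 3L)
    return(list(peak_value = max(x), peak_count = NA_real_,
                cycle_length = NA_real_, d1_sd = NA_real_))
  rng <- max(x) - min(x)
  pk <- if (rng > 0) find_peaks(x, prominence_fraction * rng) else integer(0)
  list(peak_value = max(x),
       peak_count = as.numeric(length(pk)),
       cycle_length = if (length(pk) >= 2L) mean(diff(pk)) / fs else NA_real_,
       d1_sd = sd(diff(x)) * fs)
}

#' Flat spots: longest run within one of ten equal-width force bins
#'
#' The force values are discretized into ten equal-width bins spanning
#' `[min, max]`; the statistic is the maximum run length of consecutive
#' samples falling in the same bin. A constant segment returns its length.
#'
#' @param seg A [force_segment()].
#' @param channel Analysis channel.
#' @return Integer count (as numeric).
#' @export
flat_spots <- function(seg, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  if (max(x) == min(x)) return(as.numeric(n))
  breaks <- seq(min(x), max(x), length.out = 11L)
  bins <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  as.numeric(max(rle(bins)$lengths))
}

#' Spectral statistics of a segment
#'
#' The raw periodogram of the mean-removed signal is computed by FFT over
#' the positive frequencies. `dominant_freq` is the frequency of the
#' largest ordinate; `spectral_entropy` is the Shannon entropy of the
#' normalized periodogram divided by the log of the number of ordinates,
#' in `[0, 1]` (low values = concentrated spectrum = forecastable signal).
#'
#' @param seg A [force_segment()] with at least 8 samples.
#' @param channel Analysis channel.
#' @return Named list `dominant_freq` (Hz) and `spectral_entropy`; both
#'   `NA` for zero-variance or too-short segments.
#' @export
spectral_stats <- function(seg, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  if (n < 8L || var(x) == 0)
    return(list(dominant_freq = NA_real_, spectral_entropy = NA_real_))
  xc <- x - mean(x)
  I <- Mod(fft(xc))^2 / n
  k <- seq_len(floor(n / 2))              # positive frequencies
  I <- I[k + 1L]
  freqs <- k * seg$sampling_rate / n
  p <- I / sum(I)
  p <- p[p > 0]
  list(dominant_freq = freqs[which.max(I)],
       spectral_entropy = -sum(p * log(p)) / log(length(k)))
}

# streaming leave-one-out variances: var(x[-i]) for every i in O(n)
loo_variances <- function(x) {
  n <- length(x)
  s1 <- sum(x)
  s2 <- sum(x^2)
  ((s2 - x^2) - (s1 - x)^2 / (n - 1)) / (n - 2)
}

# Terasvirta-style neural-network nonlinearity statistic (chi-squared
# form, one lag): n * R^2 of the auxiliary regression of AR(1) residuals
# on the squared and cubed lagged value; the series is standardized first
# for numerical stability
terasvirta_stat <- function(x) {
  n <- length(x)
  x <- (x - mean(x)) / sd(x)
  y <- x[-1]
  l1 <- x[-n]
  f0 <- lm(y ~ l1)
  u <- residuals(f0)
  ssr0 <- sum(u^2)
  if (ssr0 <= 0) return(NA_real_)
  f1 <- lm(u ~ l1 + I(l1^2) + I(l1^3))
  ssr1 <- sum(residuals(f1)^2)
  (n - 1) * (ssr0 - ssr1) / ssr0
}

#' Trend-decomposition statistics of a segment
#'
#' A smooth trend is estimated by local quadratic regression (loess) of
#' the force on the time index; the remainder is the signal minus that
#' trend.
#'
#' @param seg A [force_segment()] with at least 12 samples.
#' @param loess_span Loess span. Default 0.75.
#' @param channel Analysis channel.
#' @return Named list: `trend` (`max(0, 1 - var(remainder)/var(series))`),
#'   `fluctuation` (mean-crossing count divided by n-1, the dashboard's
#'   force variability index), `spikiness` (variance of the leave-one-out
#'   variances of the remainder), `linearity` (Terasvirta nonlinearity
#'   statistic) and `curvature` (second-order coefficient of an orthogonal
#'   quadratic regression on time).
#' @export
decomposition_stats <- function(seg, loess_span = 0.75, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  out <- list(trend = NA_real_, fluctuation = NA_real_,
              spikiness = NA_real_, linearity = NA_real_,
              curvature = NA_real_)
  if (n < 12L || var(x) == 0) return(out)
  tt <- (seq_len(n) - 1) / seg$sampling_rate
  fit <- stats::loess(x ~ tt, span = loess_span, degree = 2)
  rem <- residuals(fit)
  out$trend <- max(0, 1 - var(rem) / var(x))
  out$spikiness <- var(loo_variances(rem))
  out$curvature <- unname(coef(lm(x ~ poly(tt, 2)))[3])
  out$linearity <- terasvirta_stat(x)
  above <- x > mean(x)
  out$fluctuation <- sum(above[-1] != above[-n]) / (n - 1)
  out
}

#' Windowed shift statistics of a segment
#'
#' Tiled non-overlapping windows of `width` samples give `stability`
#' (variance of window means) and `lumpiness` (variance of window
#' variances). A sliding pair of adjacent `width`-sample windows gives the
#' largest absolute mean difference, variance difference and Gaussian
#' Kullback-Leibler divergence (first window relative to second, window
#' variances floored at `var_floor`).
#'
#' @param seg A [force_segment()] with at least `2 * width` samples.
#' @param width Window width in samples. Default 10.
#' @param var_floor Variance floor for the KL statistic. Default 1e-8.
#' @param channel Analysis channel.
#' @return Named list `stability`, `lumpiness`, `max_mean_shift`,
#'   `max_var_shift`, `max_kl_shift`; all `NA` when the segment is shorter
#'   than two windows.
#' @export
window_stats <- function(seg, width = 10L, var_floor = 1e-8,
                         channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  w <- as.integer(width)
  out <- list(stability = NA_real_, lumpiness = NA_real_,
              max_mean_shift = NA_real_, max_var_shift = NA_real_,
              max_kl_shift = NA_real_)
  if (n < 2L * w) return(out)
  ntile <- n %/% w
  tiles <- matrix(x[seq_len(ntile * w)], nrow = w)
  out$stability <- var(colMeans(tiles))
  out$lumpiness <- var(apply(tiles, 2, var))
  # sliding adjacent pair, O(n) via cumulative sums
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  wsum <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  wsum2 <- cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]
  mu <- wsum / w
  v <- (wsum2 - wsum^2 / w) / (w - 1)
  m1 <- mu[1:(n - 2 * w + 1)]
  m2 <- mu[(w + 1):(n - w + 1)]
  v1 <- pmax(v[1:(n - 2 * w + 1)], var_floor)
  v2 <- pmax(v[(w + 1):(n - w + 1)], var_floor)
  out$max_mean_shift <- max(abs(m2 - m1))
  out$max_var_shift <- max(abs(v2 - v1))
  out$max_kl_shift <- max(0.5 * (log(v2 / v1) + (v1 + (m1 - m2)^2) / v2 - 1))
  out
}

#' KPSS trend-stationarity statistic
#'
#' Level statistic of the Kwiatkowski-Phillips-Schmidt-Shin test with
#' linear detrending and lag-1 Bartlett long-run variance correction:
#' residuals from an OLS regression on an intercept and linear time trend
#' are partially summed, and the statistic is
#' `sum(S_t^2) / (n^2 * lrv)` with `lrv = gamma0 + gamma1` (Bartlett
#' weight 1/2 at lag one). Large values indicate non-stationarity around
#' the trend; the 10%/1% critical values for this variant are 0.119 and
#' 0.216.
#'
#' @param seg A [force_segment()] with at least 12 samples.
#' @param channel Analysis channel.
#' @return The statistic, or `NA` for too-short or zero-residual-variance
#'   segments.
#' @export
kpss_stat <- function(seg, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  if (n < 12L) return(NA_real_)
  tt <- seq_len(n)
  e <- residuals(lm(x ~ tt))
  g0 <- sum(e^2) / n
  if (g0 <= 0) return(NA_real_)
  g1 <- sum(e[-1] * e[-n]) / n
  lrv <- g0 + g1               # gamma0 + 2 * (1 - 1/2) * gamma1
  if (lrv <= 0) lrv <- g0
  S <- cumsum(e)
  sum(S^2) / (n^2 * lrv)
}

#' Autocorrelation summaries of a segment
#'
#' @param seg A [force_segment()] with at least 12 samples.
#' @param lag_max Cap on examined lags (further limited to n-1).
#' @param channel Analysis channel.
#' @return Named list: `acf_first_min_time` (seconds at the first local
#'   minimum of the ACF), `acf_first_zero_time` (seconds at the first zero
#'   crossing, linearly interpolated between lags, starting from ACF(0)=1),
#'   `acf_e1` (lag-1 coefficient) and `acf_e10` (sum of the first ten
#'   squared coefficients).
#' @export
acf_stats <- function(seg, lag_max = 100L, channel = "right") {
  x <- analysis_channel(seg, channel)
  n <- length(x)
  out <- list(acf_first_min_time = NA_real_, acf_first_zero_time = NA_real_,
              acf_e1 = NA_real_, acf_e10 = NA_real_)
  if (n < 12L || var(x) == 0) return(out)
  L <- min(n - 1L, as.integer(lag_max))
  r <- drop(acf(x, lag.max = L, plot = FALSE, demean = TRUE)$acf)[-1]
  dt <- 1 / seg$sampling_rate
  out$acf_e1 <- r[1]
  out$acf_e10 <- sum(r[seq_len(min(10L, L))]^2)
  if (L >= 2L) {
    # local minima of the ACF including lag 1 (ACF(0) = 1 is its left
    # neighbour)
    rfull0 <- c(1, r)
    mins <- which(rfull0[2:L] < rfull0[1:(L - 1)] &
                    rfull0[2:L] < rfull0[3:(L + 1)])
    if (length(mins)) out$acf_first_min_time <- mins[1] * dt
  }
  rfull <- c(1, r)              # ACF(0) = 1
  neg <- which(rfull <= 0)
  if (length(neg)) {
    k <- neg[1]                 # first lag index (1-based, lag k-1) <= 0
    if (rfull[k] == 0) {
      out$acf_first_zero_time <- (k - 1) * dt
    } else {
      a <- rfull[k - 1]
      b <- rfull[k]
      out$acf_first_zero_time <- ((k - 2) + a / (a - b)) * dt
    }
  }
  out
}

#' Extract the full 37-feature vector for every segment
#'
#' Runs all feature sub-operations on the designated analysis channel and
#' assembles exactly the [FEATURE_CATALOGUE] values per segment, joined
#' with segment metadata. Any sub-operation failure or unmet length
#' precondition degrades to `NA` for its entries; the catalogue is always
#' complete and in fixed order, and extraction is deterministic.
#'
#' @param table A [segment_table()] (preprocessed: smoothed, outliers
#'   removed).
#' @param config A [feature_config()].
#' @return A `data.frame` of class `feature_table`: metadata columns
#'   (`segment_id`, `case_id`, `task`, `surgeon_id`, `experience`) then
#'   the 37 feature columns in catalogue order.
#' @export
extract_features <- function(table, config = feature_config()) {
  stopifnot(inherits(table, "segment_table"),
            inherits(config, "feature_config"))
  ch <- config$channel
  safe <- function(expr, template) {
    tryCatch(expr, error = function(e) template)
  }
  rows <- lapply(table$segments, function(s) {
    vals <- c(
      safe(basic_stats(s, ch),
           stats::setNames(as.list(rep(NA_real_, 9)),
                           FEATURE_CATALOGUE[1:9])),
      safe(distribution_stats(s, ch),
           stats::setNames(as.list(rep(NA_real_, 6)),
                           c("skewness", "skewness_2se", "kurtosis",
                             "kurtosis_2se", "shapiro_w", "shapiro_p"))),
      safe(peak_stats(s, config$prominence_fraction, ch),
           list(peak_value = NA_real_, peak_count = NA_real_,
                cycle_length = NA_real_, d1_sd = NA_real_)),
      list(flat_spots = safe(flat_spots(s, ch), NA_real_)),
      safe(spectral_stats(s, ch),
           list(dominant_freq = NA_real_, spectral_entropy = NA_real_)),
      safe(decomposition_stats(s, config$loess_span, ch),
           list(trend = NA_real_, fluctuation = NA_real_,
                spikiness = NA_real_, linearity = NA_real_,
                curvature = NA_real_)),
      safe(window_stats(s, config$window_width, config$var_floor, ch),
           list(stability = NA_real_, lumpiness = NA_real_,
                max_mean_shift = NA_real_, max_var_shift = NA_real_,
                max_kl_shift = NA_real_)),
      list(kpss_stat = safe(kpss_stat(s, ch), NA_real_)),
      safe(acf_stats(s, config$acf_lag_max, ch),
           list(acf_first_min_time = NA_real_,
                acf_first_zero_time = NA_real_, acf_e1 = NA_real_,
                acf_e10 = NA_real_))
    )
    unlist(vals[FEATURE_CATALOGUE])
  })
  feats <- as.data.frame(do.call(rbind, rows))
  names(feats) <- FEATURE_CATALOGUE
  meta <- as.data.frame(table)
  out <- cbind(meta[, c("segment_id", "case_id", "task", "surgeon_id",
                        "experience")], feats)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as wide CSV
#'
#' Metadata columns then the 37 feature columns in catalogue order;
#' not-available values are written as empty cells.
#'
#' @param features A [extract_features()] result.
#' @param path CSV path.
#' @return `path` invisibly, or the read `feature_table`.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(FEATURE_CATALOGUE, names(df))
  if (length(missing_cols))
    stop("feature table format error: missing columns ",
         paste(missing_cols, collapse = ", "))
  class(df) <- c("feature_table", "data.frame")
  df
}
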