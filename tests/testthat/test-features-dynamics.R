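test_that("spectral statistics find the dominant frequency and entropy limits", {
  fs <- 100
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  s <- seg_of(sin(2 * pi * 1 * tt), fs = fs)
  sp <- spectral_stats(s)
  expect_equal(sp$dominant_freq, 1.0, tolerance = 0.1)
  expect_lt(sp$spectral_entropy, 0.2)

  set.seed(3)
  wn <- spectral_stats(seg_of(rnorm(1024), fs = 1))
  expect_gt(wn$spectral_entropy, 0.9)
  expect_true(wn$spectral_entropy <= 1)

  expect_true(is.na(spectral_stats(seg_of(rep(1, 64)))$dominant_freq))
})

test_that("trend decomposition separates smooth trends from noise", {
  set.seed(21)
  n <- 200
  tt <- seq_len(n)
  ramp <- seg_of(tt / n + rnorm(n, 0, 1e-4), fs = 1)
  d <- decomposition_stats(ramp)
  expect_gt(d$trend, 0.99)
  expect_lt(abs(d$curvature), 0.01)

  quad <- seg_of((tt / n - 0.5)^2, fs = 1)
  dq <- decomposition_stats(quad)
  expect_gt(dq$curvature, 0)
  quad_dn <- seg_of(-(tt / n - 0.5)^2, fs = 1)
  expect_lt(decomposition_stats(quad_dn)$curvature, 0)

  # too-short series: everything not-available
  expect_true(all(is.na(unlist(decomposition_stats(seg_of(1:5))))))
})

test_that("fluctuation is the normalized mean-crossing count", {
  x <- rep(c(0, 1), 10)              # crosses the mean every step
  d <- decomposition_stats(seg_of(x + seq_along(x) * 1e-9))
  expect_equal(d$fluctuation, 1, tolerance = 1e-6)
  set.seed(11)
  x2 <- rnorm(100)
  d2 <- decomposition_stats(seg_of(x2))
  above <- x2 > mean(x2)
  expect_equal(d2$fluctuation, sum(above[-1] != above[-100]) / 99)
})

test_that("spikiness equals the double-loop leave-one-out oracle", {
  set.seed(55)
  for (r in 1:50) {
    rem <- rnorm(sample(20:80, 1))
    # compare the internal streaming computation against the literal loop
    v <- forcetrack:::loo_variances(rem)
    manual <- vapply(seq_along(rem), function(i) var(rem[-i]), 1)
    expect_equal(v, manual, tolerance = 1e-10)
    expect_equal(var(v), oracle_spikiness(rem), tolerance = 1e-10)
  }
})

test_that("window statistics match the sliding brute-force oracle", {
  # constant series: all five are zero
  w <- window_stats(seg_of(rep(3, 40)), width = 10)
  expect_equal(unname(unlist(w)), rep(0, 5))

  # half 0 half 1 step: max mean shift of exactly 1
  step <- c(rep(0, 30), rep(1, 30))
  ws <- window_stats(seg_of(step), width = 10)
  expect_equal(ws$max_mean_shift, 1.0)

  set.seed(42)
  for (r in 1:50) {
    n <- sample(25:200, 1)
    x <- cumsum(rnorm(n))
    got <- window_stats(seg_of(x), width = 10)
    ref <- oracle_window_shifts(x, 10)
    expect_equal(got$max_mean_shift, ref$max_mean_shift, tolerance = 1e-9)
    expect_equal(got$max_var_shift, ref$max_var_shift, tolerance = 1e-9)
    expect_equal(got$max_kl_shift, ref$max_kl_shift, tolerance = 1e-9)
  }

  # below two windows everything is NA
  expect_true(all(is.na(unlist(window_stats(seg_of(1:15), width = 10)))))
})

test_that("KPSS statistic matches its from-scratch definition and is calibrated", {
  set.seed(19)
  for (r in 1:20) {
    x <- cumsum(rnorm(100)) + 0.05 * (1:100)
    expect_equal(kpss_stat(seg_of(x)), oracle_kpss(x), tolerance = 1e-10)
  }

  # size calibration: under trend-stationarity the statistic falls below
  # the 10% critical value at the nominal 90% rate (binomial 3-SE band);
  # under a random walk it exceeds the 1% critical value almost always
  n_rep <- 200L
  below <- 0L
  above <- 0L
  for (r in seq_len(n_rep)) {
    stat_ts <- kpss_stat(seg_of(rnorm(500) + 0.01 * (1:500)))
    if (stat_ts < 0.119) below <- below + 1L
    stat_rw <- kpss_stat(seg_of(cumsum(rnorm(500))))
    if (stat_rw > 0.216) above <- above + 1L
  }
  band <- 3 * sqrt(0.9 * 0.1 / n_rep)
  expect_gte(below / n_rep, 0.9 - band)
  expect_lte(below / n_rep, min(1, 0.9 + band))
  expect_gte(above / n_rep, 0.9)
})

test_that("autocorrelation summaries behave on ramps and white noise", {
  r <- acf_stats(seg_of(seq_len(1000) + 0.0, fs = 1))
  expect_gt(r$acf_e1, 0.99)

  set.seed(101)
  wn <- acf_stats(seg_of(rnorm(1000), fs = 1))
  expect_lt(abs(wn$acf_e1), 0.1)
  expect_lt(wn$acf_e10, 0.1)
  expect_gte(wn$acf_e10, wn$acf_e1^2)

  # an oscillation's first ACF minimum sits at the half period
  fs <- 20
  tt <- seq(0, 20, by = 1 / fs)
  osc <- acf_stats(seg_of(sin(2 * pi * 0.5 * tt), fs = fs))
  expect_equal(osc$acf_first_min_time, 1.0, tolerance = 0.1)
  expect_equal(osc$acf_first_zero_time, 0.5, tolerance = 0.1)
})
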