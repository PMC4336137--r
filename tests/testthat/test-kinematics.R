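test_that("resampling reproduces uniform input and interpolates linearly", {
  s <- data.frame(t_ms = seq(0, 100, 10), x = seq(0, 1, 0.1), y = 0)
  r <- resample_uniform(s, 10, 100)
  expect_equal(r$x, s$x)

  s2 <- data.frame(t_ms = c(0, 100), x = c(0, 1), y = c(0, 0))
  r2 <- resample_uniform(s2, 50, 100)
  expect_equal(r2$x[r2$t_ms == 50], 0.5)

  expect_error(resample_uniform(s, -1), "positive")
  expect_error(resample_uniform(s2[1, , drop = FALSE], 10), "2 samples")
})

test_that("resampling matches a segment-wise piecewise-linear oracle", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_trajectory(25)
    r <- resample_uniform(s, 13, 1600)
    expect_equal(r$x, oracle_interp(s$t_ms, s$x, r$t_ms), tolerance = 1e-12)
    expect_equal(r$y, oracle_interp(s$t_ms, s$y, r$t_ms), tolerance = 1e-12)
  }
})

test_that("differentiation is exact on low-degree polynomials", {
  dt <- 10
  t <- seq(0, 1000, dt)
  # constant
  k0 <- differentiate(data.frame(t_ms = t, x = rep(2, length(t)), y = 0), dt)
  expect_equal(k0$vx, rep(0, length(t)))
  expect_equal(k0$ax, rep(0, length(t)))
  # linear: x = c * t  (c in units/ms -> vx in units/s)
  cc <- 0.003
  k1 <- differentiate(data.frame(t_ms = t, x = cc * t, y = 0), dt)
  interior <- 2:(length(t) - 1)
  expect_equal(k1$vx[interior], rep(cc * 1000, length(interior)), tolerance = 1e-12)
  # quadratic: x = a/2 t^2 -> ax = a (central differences are exact)
  a <- 2e-6  # units/ms^2 -> 2 units/s^2
  k2 <- differentiate(data.frame(t_ms = t, x = a / 2 * t^2, y = 0), dt)
  inner <- 3:(length(t) - 2)
  expect_equal(k2$ax[inner], rep(a * 1e6, length(inner)), tolerance = 1e-9)
  expect_error(differentiate(data.frame(t_ms = 1:2, x = 1:2, y = 0), 1),
               "3 grid points")
})

test_that("onset detection finds the first eleven-point increasing run", {
  t <- seq(0, by = 13, length.out = 13)
  s <- data.frame(t_ms = t, vx = 0:12)
  expect_equal(detect_onset(s, 11), 0)

  alt <- data.frame(t_ms = seq(0, by = 13, length.out = 40),
                    vx = rep(c(0, 1), 20))
  expect_true(is.na(detect_onset(alt, 11)))

  # planted run at index 37 in an otherwise non-increasing series
  set.seed(5)
  vx <- rep(c(1, 0), 30)[1:60]
  vx[37:47] <- seq(2, 12)          # 11 strictly increasing points
  vx[36] <- 5                      # block the run from starting one earlier
  s3 <- data.frame(t_ms = seq(0, by = 13, length.out = 60), vx = vx)
  expect_equal(detect_onset(s3, 11), s3$t_ms[37])
  expect_equal(detect_onset(s3, 11), oracle_onset(s3$t_ms, vx, 11))

  expect_error(detect_onset(s, 1), "run_length")
})

test_that("onset detection agrees with a brute-force window scan on random series", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(30:120, 1)
    vx <- cumsum(stats::rnorm(n))
    t <- seq(0, by = 13, length.out = n)
    k <- sample(c(3, 5, 11), 1)
    got <- detect_onset(data.frame(t_ms = t, vx = vx), k)
    want <- oracle_onset(t, vx, k)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(want)) expect_equal(got, want)
  }
})

test_that("peaks of a minimum-jerk reach fall where the closed form predicts", {
  L <- 200; D <- 700
  tr <- simulate_trial(noise_free_params(competitor_weight = 0,
                                         onset_latency_ms = c(L, 0),
                                         movement_duration_ms = c(D, 0)),
                       "HF", "continuous", seed = 2)
  k <- differentiate(resample_uniform(tr$samples, 13, 2000), 13)
  onset <- detect_onset(k, 11)
  ev <- detect_peaks(k, onset, 2000)
  # velocity peak at L + D/2 within one bin
  expect_lte(abs(ev$vpeak_ms - (L + D / 2)), 13)
  # acceleration peak before velocity peak before deceleration peak
  expect_lt(ev$apeak_ms, ev$vpeak_ms)
  expect_lt(ev$vpeak_ms, ev$dpeak_ms)
  expect_gte(ev$apeak, 0)
  expect_lte(ev$dpeak, 0)
  expect_equal(ev$vpeak_latency_ms, ev$vpeak_ms - onset)
  # movement time: cursor inside the capture region through the end
  expect_gte(ev$movement_time_ms, L)
  expect_lte(ev$movement_time_ms, L + D + 30)
  expect_error(detect_peaks(k, NA_real_), "onset")
})

test_that("amplitudes scale with position while event times are invariant", {
  tr <- simulate_trial(noise_free_params(), "LF", "continuous", seed = 6)
  k1 <- differentiate(resample_uniform(tr$samples, 13, 2000), 13)
  s <- tr$samples
  s$x <- 3 * s$x; s$y <- 3 * s$y
  k3 <- differentiate(resample_uniform(s, 13, 2000), 13)
  expect_equal(k3$vx, 3 * k1$vx, tolerance = 1e-12)
  expect_equal(k3$ax, 3 * k1$ax, tolerance = 1e-12)
  expect_equal(which.max(k3$vx), which.max(k1$vx))
  expect_equal(which.max(k3$ax), which.max(k1$ax))
})

test_that("time reversal mirrors acceleration and deceleration peaks", {
  dt <- 10
  t <- seq(0, 1000, dt)
  x <- mousekin:::min_jerk_s(t / 1000)  # symmetric bell velocity
  kf <- differentiate(data.frame(t_ms = t, x = x, y = 0), dt)
  kb <- differentiate(data.frame(t_ms = t, x = rev(x), y = 0), dt)
  # the symmetric bell's acceleration is antisymmetric, so replaying the
  # movement backwards puts the acceleration peak at the old deceleration time
  expect_equal(t[which.max(kb$ax)], t[which.min(kf$ax)])
  expect_equal(t[which.min(kb$ax)], t[which.max(kf$ax)])
  expect_equal(max(kb$ax), -min(kf$ax), tolerance = 1e-9)
})

test_that("double-peak detection separates constructed one- and two-bump profiles", {
  t <- seq(0, 1500, 13)
  bump <- function(mu, amp, sd = 60) amp * exp(-(t - mu)^2 / (2 * sd^2))
  # single bell -> no double peak
  single <- detect_double_peak(bump(400, 10), t)
  expect_false(single$double_peak)
  # two bumps with an inter-peak trough staying positive
  two_pos <- bump(400, 10) + bump(650, 6) + 1
  r1 <- detect_double_peak(two_pos, t)
  expect_true(r1$double_peak)
  expect_lte(abs(r1$second_apeak_ms - 650), 13)
  expect_false(r1$trough_crosses_zero)
  # two bumps separated by a negative trough
  two_neg <- bump(400, 10) - bump(525, 4) + bump(650, 6)
  r2 <- detect_double_peak(two_neg, t)
  expect_true(r2$double_peak)
  expect_true(r2$trough_crosses_zero)
  # peaks verified by an exhaustive local-maximum scan
  lm <- which(diff(sign(diff(two_neg))) == -2) + 1
  expect_equal(sort(c(r2$apeak_ms, r2$second_apeak_ms)), sort(t[lm]))
  # a small wiggle below prominence does not count
  wiggle <- bump(400, 10) + bump(700, 1.5)
  expect_false(detect_double_peak(wiggle, t, prominence_frac = 0.25)$double_peak)
  expect_error(detect_double_peak(rep(0, 10), seq_len(10)), "all-zero")
})
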