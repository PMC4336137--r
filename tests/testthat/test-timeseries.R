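mk_series <- function(values, cond = "HF", measure = "vx", bin = 39) {
  structure(list(condition = cond, measure = measure,
                 t_ms = (seq_along(values) - 1) * bin, values = values,
                 n = 1L), class = "condition_series")
}

test_that("condition means average trials pointwise and record n", {
  tr <- simulate_trial(noise_free_params(competitor_weight = 0), "HF",
                       "continuous", seed = 1)
  k <- differentiate(resample_uniform(tr$samples, 13, 2000), 13)
  kin <- list(a = k, b = k, c = k)
  meta <- data.frame(trial_id = c("a", "b", "c"),
                     condition = c("HF", "HF", "LF"))
  m <- condition_mean_series(kin, meta, "HF", "vx")
  expect_equal(m$n, 2L)
  expect_equal(length(m$values), 50L)
  # identical trials: the mean is any one of them
  expect_equal(m$values, stats::approx(k$t_ms, k$vx, xout = m$t_ms)$y)

  k2 <- k; k2$vx <- k$vx + 1
  m2 <- condition_mean_series(list(a = k, b = k2),
                              data.frame(trial_id = c("a", "b"),
                                         condition = c("HF", "HF")),
                              "HF", "vx")
  expect_equal(m2$values,
               stats::approx(k$t_ms, k$vx + 0.5, xout = m2$t_ms)$y)
  expect_error(condition_mean_series(kin, meta, "PW", "vx"), "no trials")
})

test_that("cross-correlation of a series with itself peaks at lag zero", {
  set.seed(3)
  a <- mk_series(stats::rnorm(50))
  r <- cross_correlate(a, a, 10)
  expect_equal(r$r[r$lags == 0], 1)
  expect_equal(r$best_lag, 0L)
  expect_true(all(abs(r$r) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("a series delayed by j bins is recovered at best_lag = -j", {
  base <- exp(-(seq(0, 49) - 15)^2 / 30)   # smooth bump
  for (j in c(1L, 2L, 5L)) {
    delayed <- c(rep(base[1], j), base[1:(50 - j)])
    r <- cross_correlate(mk_series(base), mk_series(delayed, "PW"), 10)
    expect_equal(r$best_lag, -j)
    # and symmetrically, an anticipated series gives +j
    r2 <- cross_correlate(mk_series(delayed, "PW"), mk_series(base), 10)
    expect_equal(r2$best_lag, j)
  }
})

test_that("cross-correlation matches a direct Pearson oracle at every lag", {
  set.seed(9)
  for (i in 1:20) {
    a <- mk_series(stats::rnorm(50))
    b <- mk_series(stats::rnorm(50), "LF")
    r <- cross_correlate(a, b, 12)
    for (l in r$lags) {
      expect_equal(r$r[r$lags == l], oracle_ccf_lag(a$values, b$values, l),
                   tolerance = 1e-10)
    }
    # symmetry: r_ab(l) == r_ba(-l)
    rba <- cross_correlate(b, a, 12)
    expect_equal(r$r, rev(rba$r), tolerance = 1e-12)
  }
})

test_that("degenerate series are rejected", {
  cst <- mk_series(rep(1, 50))
  ok <- mk_series(stats::rnorm(50))
  expect_error(cross_correlate(cst, ok), "zero-variance")
  short <- mk_series(stats::rnorm(10))
  expect_error(cross_correlate(ok, short), "grids differ")
})

test_that("window means use the half-open convention", {
  t50 <- seq(0, 1950, 50)
  v <- rep(3.25, length(t50))
  expect_equal(window_mean(v, t50, c(400, 700)), 3.25)
  # [400, 700) on 50 ms bins averages exactly 6 bins
  expect_equal(sum(t50 >= 400 & t50 < 700), 6L)
  v2 <- seq_along(t50)
  expect_equal(window_mean(v2, t50, c(400, 700)), mean(v2[t50 >= 400 & t50 < 700]))
  set.seed(12)
  for (i in 1:30) {
    vr <- stats::rnorm(length(t50))
    w <- sort(sample(seq(0, 1900, 50), 2))
    if (w[1] == w[2]) next
    expect_equal(window_mean(vr, t50, w), oracle_window_mean(vr, t50, w),
                 tolerance = 1e-12)
  }
  expect_error(window_mean(v, t50, c(3000, 3100)), "empty window")
})
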