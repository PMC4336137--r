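# Independent brute-force oracles used to validate the analytic operations,
# deliberately written with different algorithms than the implementations.

# signed deviation of the sample farthest from the first->last line,
# computed pointwise via vector projection
oracle_max_deviation <- function(x, y) {
  n <- length(x)
  p1 <- c(x[1], y[1])
  u <- c(x[n] - x[1], y[n] - y[1])
  u <- u / sqrt(sum(u^2))
  d <- numeric(n)
  for (i in seq_len(n)) {
    v <- c(x[i], y[i]) - p1
    proj <- sum(v * u) * u
    perp <- v - proj
    s <- sign(u[1] * v[2] - u[2] * v[1])
    d[i] <- s * sqrt(sum(perp^2))
  }
  d[which.max(abs(d))]
}

# naive O(n*k) window scan for the first strictly increasing run
oracle_onset <- function(t_ms, vx, run_length) {
  n <- length(vx)
  for (i in seq_len(max(0, n - run_length + 1))) {
    w <- vx[i:(i + run_length - 1)]
    if (all(diff(w) > 0)) return(t_ms[i])
  }
  NA_real_
}

# Pearson correlation at one lag, r(l) = cor(a[t], b[t - l]), built from an
# explicit index list
oracle_ccf_lag <- function(a, b, l) {
  n <- length(a)
  idx_a <- integer(0); idx_b <- integer(0)
  for (t in seq_len(n)) {
    if (t - l >= 1 && t - l <= n) {
      idx_a <- c(idx_a, t); idx_b <- c(idx_b, t - l)
    }
  }
  stats::cor(a[idx_a], b[idx_b])
}

# direct index-and-average window mean
oracle_window_mean <- function(values, t_ms, window) {
  acc <- 0; k <- 0
  for (i in seq_along(values)) {
    if (t_ms[i] >= window[1] && t_ms[i] < window[2]) {
      acc <- acc + values[i]; k <- k + 1
    }
  }
  acc / k
}

# segment-wise piecewise-linear evaluation
oracle_interp <- function(t, v, q) {
  sapply(q, function(qq) {
    if (qq <= t[1]) return(v[1])
    if (qq >= t[length(t)]) return(v[length(v)])
    j <- max(which(t <= qq))
    if (t[j] == qq) return(v[j])
    v[j] + (v[j + 1] - v[j]) * (qq - t[j]) / (t[j + 1] - t[j])
  })
}

# random nonuniform trajectory for oracle checks
random_trajectory <- function(n = 30) {
  t_ms <- sort(stats::runif(n, 0, 1500))
  t_ms <- t_ms + seq(0, 1, length.out = n)  # enforce strict increase
  data.frame(t_ms = t_ms, x = cumsum(stats::rnorm(n, 0.03, 0.05)),
             y = cumsum(stats::rnorm(n, 0.05, 0.05)))
}
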