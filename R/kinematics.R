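# Kinematic profiling: uniform resampling, numerical differentiation,
# movement onset, velocity/acceleration peaks, and double-peak detection.

#' Resample a trajectory onto a uniform time grid
#'
#' Linear interpolation onto the grid \code{0, dt, 2*dt, ...} up to
#' \code{t_max}. The position is held constant beyond the recorded samples
#' (cursor at rest on the start button before the first sample and on the
#' target after movement end), so condition means over a fixed window remain
#' defined for trials of different durations.
#'
#' @param samples data.frame with \code{t_ms}, \code{x}, \code{y} (raw
#'   timestamps need not be uniform).
#' @param dt_ms grid spacing in ms (default 13 ms, close to the ~70 Hz
#'   hardware sampling).
#' @param t_max_ms end of the grid in ms.
#' @return data.frame with uniform \code{t_ms}, \code{x}, \code{y}.
#' @export
resample_uniform <- function(samples, dt_ms = 13, t_max_ms = 2000) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  if (nrow(samples) < 2) stop("need at least 2 samples")
  grid <- seq(0, t_max_ms, by = dt_ms)
  data.frame(t_ms = grid,
             x = stats::approx(samples$t_ms, samples$x, xout = grid, rule = 2)$y,
             y = stats::approx(samples$t_ms, samples$y, xout = grid, rule = 2)$y)
}

# central differences inside, one-sided at the ends; dt in seconds
finite_diff <- function(v, dt_s) {
  n <- length(v)
  if (n < 3) stop("need at least 3 grid points to differentiate")
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / dt_s
  d[n] <- (v[n] - v[n - 1]) / dt_s
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_s)
  d
}

#' Differentiate a uniform position series into a kinematic series
#'
#' Velocities by central differences (one-sided at the boundaries), then
#' accelerations by differentiating the velocities. The Euclidean speed
#' \code{v_euclid = sqrt(vx^2 + vy^2)} and its derivative \code{a_euclid} are
#' used for the reversal analysis; \code{vx}/\code{ax} carry the left-right
#' decision signal. Units: normalized units per second (and per second^2).
#'
#' @param series data.frame from \code{\link{resample_uniform}}.
#' @param dt_ms grid spacing in ms.
#' @param smooth_passes number of passes of a 3-point moving average applied
#'   to the positions before differentiating (0 = none, the default; the
#'   raw definitions are used unless noise robustness is required).
#' @return The input with columns \code{vx, vy, ax, v_euclid, a_euclid} added,
#'   class \code{kinematic_series}.
#' @export
differentiate <- function(series, dt_ms, smooth_passes = 0) {
  dt_s <- dt_ms / 1000
  x <- smooth_ma3(series$x, smooth_passes)
  y <- smooth_ma3(series$y, smooth_passes)
  vx <- finite_diff(x, dt_s)
  vy <- finite_diff(y, dt_s)
  v_euclid <- sqrt(vx^2 + vy^2)
  out <- series
  out$vx <- vx
  out$vy <- vy
  out$ax <- finite_diff(vx, dt_s)
  out$v_euclid <- v_euclid
  out$a_euclid <- finite_diff(v_euclid, dt_s)
  class(out) <- c("kinematic_series", "data.frame")
  out
}

# k passes of a centered 3-point moving average (endpoints kept)
smooth_ma3 <- function(v, passes = 1) {
  if (passes <= 0) return(v)
  n <- length(v)
  for (i in seq_len(passes)) {
    v <- c(v[1], (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3, v[n])
  }
  v
}

#' Per-trial kinematic series for a trial set
#'
#' @param trials a normalized \code{trial_set}.
#' @param dt_ms grid spacing in ms.
#' @param t_max_ms end of the common grid.
#' @param smooth_passes passed to \code{\link{differentiate}}.
#' @return Named list of \code{kinematic_series}, one per trial.
#' @export
trial_kinematics <- function(trials, dt_ms = 13, t_max_ms = 2000,
                             smooth_passes = 0) {
  stopifnot(inherits(trials, "trial_set"))
  ss <- split(trials$samples, trials$samples$trial_id)
  ids <- unique(trials$samples$trial_id)
  out <- lapply(ids, function(id)
    differentiate(resample_uniform(ss[[id]], dt_ms, t_max_ms), dt_ms,
                  smooth_passes))
  names(out) <- ids
  out
}

#' Detect movement onset
#'
#' Onset is the time of the first sample that begins a run of
#' \code{run_length} strictly increasing consecutive x-velocity values
#' (default: eleven increasing points).
#'
#' @param series a \code{kinematic_series} (or any data.frame with
#'   \code{t_ms} and \code{vx}).
#' @param run_length minimum run of increasing velocity samples (>= 2).
#' @return Onset time in ms, or \code{NA_real_} if no qualifying run exists.
#' @export
detect_onset <- function(series, run_length = 11) {
  if (run_length < 2) stop("run_length must be >= 2")
  vx <- series$vx
  inc <- diff(vx) > 0
  need <- run_length - 1L          # increments in a run of run_length points
  if (length(inc) < need) return(NA_real_)
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(NA_real_)
  series$t_ms[starts[hit[1]]]
}

#' Extract movement events from a kinematic series
#'
#' Within the window from movement onset to the deadline: the velocity peak
#' (maximum \code{vx}), acceleration peak (maximum \code{ax}) and
#' deceleration peak (minimum \code{ax}), with latencies measured from onset.
#' Movement time is the first grid time at which the cursor enters the target
#' capture region and stays there.
#'
#' @param series a \code{kinematic_series} of a normalized trial.
#' @param onset_ms movement onset (from \code{\link{detect_onset}}).
#' @param deadline_ms end of the search window.
#' @param geometry an \code{\link{mt_geometry}} (target position and capture
#'   radius used for movement time).
#' @return One-row data.frame with onset, movement time, peak times,
#'   amplitudes and latencies.
#' @export
detect_peaks <- function(series, onset_ms, deadline_ms = 2000,
                         geometry = mt_geometry()) {
  if (is.na(onset_ms)) stop("no-movement trial: onset is absent")
  w <- series$t_ms >= onset_ms & series$t_ms <= deadline_ms
  t <- series$t_ms[w]
  vx <- series$vx[w]; ax <- series$ax[w]
  iv <- which.max(vx); ia <- which.max(ax); id <- which.min(ax)
  d2 <- (series$x - geometry$target[1])^2 + (series$y - geometry$target[2])^2
  inside <- d2 <= geometry$capture_radius^2
  # first index from which the cursor never leaves the capture region
  stay <- rev(cumprod(rev(inside))) > 0
  mt <- if (any(stay)) series$t_ms[which(stay)[1]] else NA_real_
  data.frame(onset_ms = onset_ms,
             movement_time_ms = mt,
             vpeak_ms = t[iv], vpeak = vx[iv],
             apeak_ms = t[ia], apeak = ax[ia],
             dpeak_ms = t[id], dpeak = ax[id],
             vpeak_latency_ms = t[iv] - onset_ms,
             apeak_latency_ms = t[ia] - onset_ms,
             dpeak_latency_ms = t[id] - onset_ms)
}

# local maxima (strict left, non-strict right to tolerate plateaus)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# topographic prominence of peak i: height above the higher of the two
# lowest points separating it from higher ground on each side
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- if (i == 1) v[1] else {
    higher <- which(v[1:(i - 1)] > v[i])
    lo <- if (length(higher)) (max(higher) + 1L) else 1L
    min(v[lo:i])
  }
  right <- if (i == n) v[n] else {
    higher <- which(v[(i + 1):n] > v[i])
    hi <- if (length(higher)) (i + min(higher) - 1L) else n
    min(v[i:hi])
  }
  v[i] - max(left, right)
}

#' Detect a double acceleration peak
#'
#' A change-of-mind signature: at least two positive local maxima in the
#' acceleration profile, each with topographic prominence of at least
#' \code{prominence_frac} times the profile's global maximum, occurring
#' before the final sustained deceleration trough (a qualifying negative
#' trough followed by no further qualifying positive peak). Also reports
#' whether the trough between the first two qualifying peaks dips below zero
#' (a full brake) or not (a deflection that rises again).
#'
#' @param a acceleration values (use \code{ax} for condition means, or
#'   \code{a_euclid} for the per-trial reversal analysis).
#' @param t_ms time grid matching \code{a}.
#' @param prominence_frac minimum peak prominence relative to the global
#'   maximum.
#' @param smooth_passes passes of a 3-point moving average applied to
#'   \code{a} before peak picking (noise guard for per-trial profiles;
#'   0 disables).
#' @return list with \code{double_peak}, \code{n_peaks},
#'   \code{apeak_ms}/\code{apeak}, \code{second_apeak_ms}/\code{second_apeak}
#'   (NA when absent) and \code{trough_crosses_zero}.
#' @export
detect_double_peak <- function(a, t_ms, prominence_frac = 0.25,
                               smooth_passes = 0) {
  stopifnot(length(a) == length(t_ms))
  if (all(a == 0)) stop("all-zero acceleration series")
  a <- smooth_ma3(a, smooth_passes)
  gmax <- max(a)
  thr <- prominence_frac * gmax
  cand <- local_maxima(a)
  cand <- cand[a[cand] > 0]
  peaks <- cand[vapply(cand, function(i) peak_prominence(a, i), numeric(1)) >= thr]
  trough_cand <- local_maxima(-a)
  trough_cand <- trough_cand[a[trough_cand] < 0]
  troughs <- trough_cand[vapply(trough_cand, function(i) peak_prominence(-a, i),
                                numeric(1)) >= thr]
  # final sustained deceleration: last qualifying trough with no peak after it
  if (length(troughs) && length(peaks)) {
    final_tr <- troughs[troughs > max(peaks)]
    if (length(final_tr)) peaks <- peaks[peaks < min(final_tr)]
  }
  n <- length(peaks)
  res <- list(double_peak = n >= 2, n_peaks = n,
              apeak_ms = NA_real_, apeak = NA_real_,
              second_apeak_ms = NA_real_, second_apeak = NA_real_,
              trough_crosses_zero = NA)
  if (n >= 1) {
    res$apeak_ms <- t_ms[peaks[1]]
    res$apeak <- a[peaks[1]]
  }
  if (n >= 2) {
    res$second_apeak_ms <- t_ms[peaks[2]]
    res$second_apeak <- a[peaks[2]]
    res$trough_crosses_zero <- min(a[peaks[1]:peaks[2]]) < 0
  }
  res
}

#' Count qualifying positive peaks and negative troughs
#'
#' Used to check the "butterfly" shape of condition-mean acceleration
#' profiles: one prominent positive peak followed by one prominent negative
#' trough.
#'
#' @inheritParams detect_double_peak
#' @return list with \code{n_pos_peaks}, \code{n_neg_troughs} and the index
#'   vectors.
#' @export
count_accel_events <- function(a, t_ms, prominence_frac = 0.25,
                               smooth_passes = 0) {
  a <- smooth_ma3(a, smooth_passes)
  scale <- max(abs(a))
  thr <- prominence_frac * scale
  pk <- local_maxima(a)
  pk <- pk[a[pk] > 0]
  pk <- pk[vapply(pk, function(i) peak_prominence(a, i), numeric(1)) >= thr]
  tr <- local_maxima(-a)
  tr <- tr[a[tr] < 0]
  tr <- tr[vapply(tr, function(i) peak_prominence(-a, i), numeric(1)) >= thr]
  list(n_pos_peaks = length(pk), n_neg_troughs = length(tr),
       peak_t_ms = t_ms[pk], trough_t_ms = t_ms[tr])
}
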