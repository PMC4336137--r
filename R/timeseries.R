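# Condition-mean kinematic time-series and their lagged cross-correlation.

#' Condition-mean kinematic series
#'
#' Pointwise mean of one kinematic measure across the retained trials of a
#' condition, on a coarse common grid (default 50 bins of 39 ms covering
#' [0, 1950) ms). Trials are padded at rest after movement end by
#' construction of \code{\link{resample_uniform}}.
#'
#' @param kin named list of per-trial \code{kinematic_series}
#'   (from \code{\link{trial_kinematics}}).
#' @param meta the \code{trials} data.frame of the trial set.
#' @param condition condition label to average.
#' @param measure column to average (\code{"vx"}, \code{"ax"},
#'   \code{"v_euclid"}, \code{"a_euclid"}, ...).
#' @param bin_ms bin width of the common grid.
#' @param n_bins number of bins.
#' @return list of class \code{condition_series}: \code{condition, measure,
#'   t_ms, values, n}.
#' @export
condition_mean_series <- function(kin, meta, condition, measure = "vx",
                                  bin_ms = 39, n_bins = 50) {
  ids <- meta$trial_id[meta$condition == condition]
  ids <- ids[ids %in% names(kin)]
  if (length(ids) == 0) stop("no trials for condition ", condition)
  grid <- (seq_len(n_bins) - 1L) * bin_ms
  m <- vapply(ids, function(id) {
    s <- kin[[id]]
    stats::approx(s$t_ms, s[[measure]], xout = grid, rule = 2)$y
  }, numeric(n_bins))
  structure(list(condition = condition, measure = measure, t_ms = grid,
                 values = rowMeans(m), n = length(ids)),
            class = "condition_series")
}

#' @export
print.condition_series <- function(x, ...) {
  cat(sprintf("condition_series %s (%s): %d bins x %.0f ms, n = %d trials\n",
              x$condition, x$measure, length(x$t_ms),
              if (length(x$t_ms) > 1) diff(x$t_ms[1:2]) else NA, x$n))
  invisible(x)
}

#' Lagged cross-correlation of two condition series
#'
#' Pearson correlation of the overlapping segments of the two series at each
#' integer lag in \code{-max_lag..max_lag}, with means and standard
#' deviations computed on each truncated segment (local normalization, so
#' every value lies in [-1, 1]). Sign convention: a negative best lag means
#' the second series must be shifted \emph{earlier} (anticipated) to align
#' with the first — a series delayed by j bins relative to the reference
#' yields best_lag = -j when passed as \code{b}.
#'
#' @param a,b \code{condition_series} on identical grids.
#' @param max_lag maximum lag in bins (clipped so at least 3 points overlap).
#' @return list of class \code{ccf_result}: \code{lags}, \code{r},
#'   \code{best_lag}, \code{best_r}, \code{bin_ms}.
#' @export
cross_correlate <- function(a, b, max_lag = 50) {
  stopifnot(inherits(a, "condition_series"), inherits(b, "condition_series"))
  if (length(a$t_ms) != length(b$t_ms) || any(a$t_ms != b$t_ms))
    stop("series grids differ")
  va <- a$values; vb <- b$values
  n <- length(va)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero-variance series: correlation undefined")
  K <- min(max_lag, n - 3L)
  lags <- -K:K
  r <- vapply(lags, function(l) {
    # r(l) = cor(a[t], b[t - l]) over the overlap
    if (l >= 0) {
      sa <- va[(1 + l):n]; sb <- vb[1:(n - l)]
    } else {
      sa <- va[1:(n + l)]; sb <- vb[(1 - l):n]
    }
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(NA_real_)
    stats::cor(sa, sb)
  }, numeric(1))
  ok <- which(!is.na(r))
  best <- ok[order(-r[ok], abs(lags[ok]))][1]
  structure(list(lags = lags, r = r, best_lag = lags[best], best_r = r[best],
                 bin_ms = if (length(a$t_ms) > 1) diff(a$t_ms[1:2]) else NA,
                 pair = c(a$condition, b$condition), measure = a$measure),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("ccf %s-%s (%s): r(0) = %.3f, best r = %.3f at lag %d (%.0f ms/lag)\n",
              x$pair[1], x$pair[2], x$measure, x$r[x$lags == 0], x$best_r,
              x$best_lag, x$bin_ms))
  invisible(x)
}

#' Mean of a series over a half-open time window
#'
#' Averages the values whose bin start times lie in \code{[a, b)}. The
#' half-open convention keeps adjacent and overlapping analysis windows
#' unambiguous.
#'
#' @param values series values.
#' @param t_ms bin start times.
#' @param window numeric length-2, \code{c(a_ms, b_ms)}.
#' @return scalar mean.
#' @export
window_mean <- function(values, t_ms, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  sel <- t_ms >= window[1] & t_ms < window[2]
  if (!any(sel)) stop("empty window [", window[1], ", ", window[2], ")")
  mean(values[sel])
}

#' Per-trial window means
#'
#' @param kin named list of per-trial \code{kinematic_series}.
#' @param ids trial ids to include.
#' @param measure series column.
#' @param window half-open window \code{c(a_ms, b_ms)}.
#' @return named numeric vector of per-trial means.
#' @export
trial_window_means <- function(kin, ids, measure, window) {
  vapply(ids, function(id)
    window_mean(kin[[id]][[measure]], kin[[id]]$t_ms, window), numeric(1))
}
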