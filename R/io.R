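# Reading, validation, normalization and exclusion filtering of trial data.

#' Read trials from a CSV export
#'
#' Long format expects the canonical header
#' \code{trial_id,participant,condition,correct,timeout,t_ms,x,y}; wide format
#' expects MouseTracker-style columns \code{X_1..X_101,Y_1..Y_101,rt_ms} and
#' reconstructs a uniform grid of 101 samples spaced \code{rt_ms/100} apart.
#' Timestamps must be strictly increasing within a trial; a violation aborts
#' with the offending \code{trial_id}.
#'
#' The response side is recovered from the sign of the final x coordinate
#' (the side the cursor ended on).
#'
#' @param path CSV file written by \code{\link{write_dataset}} or an
#'   equivalent export.
#' @param format \code{"long_csv"} or \code{"wide_csv"}.
#' @return A \code{trial_set}.
#' @export
read_trials <- function(path, format = c("long_csv", "wide_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long_csv") {
    need <- c("trial_id", "participant", "condition", "correct", "timeout",
              "t_ms", "x", "y")
    if (!all(need %in% names(df)))
      stop("malformed header: expected columns ", paste(need, collapse = ","))
    ids <- unique(df$trial_id)
    trials <- lapply(ids, function(id) {
      s <- df[df$trial_id == id, ]
      if (nrow(s) < 2) stop("trial ", id, " has fewer than 2 samples")
      if (any(diff(s$t_ms) <= 0))
        stop("non-monotone timestamps in trial ", id)
      side <- if (s$x[nrow(s)] >= 0) "right" else "left"
      structure(list(trial_id = id, participant = s$participant[1],
                     condition = s$condition[1], correct = as.logical(s$correct[1]),
                     timeout = as.logical(s$timeout[1]), response_side = side,
                     rt_ms = max(s$t_ms),
                     samples = data.frame(t_ms = s$t_ms, x = s$x, y = s$y)),
                class = "mt_trial")
    })
  } else {
    xcols <- paste0("X_", 1:101); ycols <- paste0("Y_", 1:101)
    need <- c("trial_id", "participant", "condition", "correct", "timeout",
              xcols, ycols, "rt_ms")
    if (!all(need %in% names(df)))
      stop("malformed header: wide format requires X_1..X_101, Y_1..Y_101, rt_ms")
    trials <- lapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      t_ms <- seq(0, r$rt_ms, length.out = 101)
      x <- as.numeric(r[xcols]); y <- as.numeric(r[ycols])
      side <- if (x[101] >= 0) "right" else "left"
      structure(list(trial_id = r$trial_id, participant = r$participant,
                     condition = r$condition, correct = as.logical(r$correct),
                     timeout = as.logical(r$timeout), response_side = side,
                     rt_ms = r$rt_ms,
                     samples = data.frame(t_ms = t_ms, x = x, y = y)),
                class = "mt_trial")
    })
  }
  bad <- !vapply(trials, function(tr) tr$condition %in% CONDITIONS, logical(1))
  if (any(bad))
    stop("invalid condition label in trials: ",
         paste(vapply(trials[bad], `[[`, "", "trial_id"), collapse = ", "))
  new_trial_set(trials, normalized = FALSE)
}

#' Normalize and mirror trajectories
#'
#' Maps raw coordinates into the standard mouse-tracking space: start button
#' at the origin, response buttons at (+/-1, 1.5), y increasing toward the
#' buttons, and every trial mirrored so its \emph{correct} response lies at
#' x = +1. For screen-pixel input supply the pixel geometry (\code{target} =
#' right-hand button, \code{competitor} = left-hand button); screen-down y
#' axes are handled automatically by the sign of the y scale. The default
#' geometry is the identity for data already in normalized coordinates, in
#' which case normalizing twice is a no-op.
#'
#' @param trials a \code{trial_set}.
#' @param geometry an \code{\link{mt_geometry}} giving the raw positions of
#'   the start button and the right/left response buttons.
#' @return A normalized, mirrored \code{trial_set}.
#' @export
normalize_trials <- function(trials, geometry = mt_geometry()) {
  stopifnot(inherits(trials, "trial_set"))
  if (isTRUE(trials$normalized)) return(trials)   # idempotent
  sx <- geometry$target[1] - geometry$start[1]
  sy <- geometry$target[2] - geometry$start[2]
  if (sx == 0 || sy == 0) stop("degenerate geometry: start equals target")
  s <- trials$samples
  meta <- trials$trials[match(s$trial_id, trials$trials$trial_id), ]
  x <- (s$x - geometry$start[1]) / abs(sx)
  y <- (s$y - geometry$start[2]) / sy * 1.5
  # mirror so the correct button is at x = +1
  chosen_left <- meta$response_side == "left"
  correct_left <- ifelse(meta$correct, chosen_left, !chosen_left)
  x <- ifelse(correct_left, -x, x)
  out <- trials
  out$samples$x <- x
  out$samples$y <- y
  out$normalized <- TRUE
  out
}

#' Exclusion report
#'
#' @param n_total,n_timeout,n_error,n_retained disjoint trial counts
#'   (timeout takes precedence over error).
#' @return A list of class \code{exclusion_report} with counts and rates.
#' @export
exclusion_report <- function(n_total, n_timeout, n_error, n_retained) {
  stopifnot(n_retained == n_total - n_timeout - n_error)
  structure(list(n_total = n_total, n_timeout = n_timeout, n_error = n_error,
                 n_retained = n_retained,
                 rates = c(timeout = n_timeout / n_total,
                           error = n_error / n_total,
                           retained = n_retained / n_total)),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("exclusions: %d trials; %d timeout (%.1f%%), %d error (%.1f%%), %d retained (%.1f%%)\n",
              x$n_total, x$n_timeout, 100 * x$rates["timeout"],
              x$n_error, 100 * x$rates["error"],
              x$n_retained, 100 * x$rates["retained"]))
  invisible(x)
}

#' Apply trial exclusions
#'
#' Removes trials whose final sample exceeds the response deadline
#' (timeouts), then incorrect responses, in that order of precedence, so the
#' reported categories are disjoint and their counts conserve:
#' \code{n_timeout + n_error + n_retained == n_total}. Only correct,
#' within-deadline trials enter the kinematic analyses.
#'
#' @param trials a \code{trial_set}.
#' @param deadline_ms response deadline in ms.
#' @return list with \code{trials} (the retained \code{trial_set}) and
#'   \code{report} (an \code{\link{exclusion_report}}).
#' @export
apply_exclusions <- function(trials, deadline_ms = 2000) {
  stopifnot(inherits(trials, "trial_set"))
  if (nrow(trials$trials) == 0) stop("empty trial set")
  t_final <- vapply(split(trials$samples$t_ms, trials$samples$trial_id), max,
                    numeric(1))[trials$trials$trial_id]
  is_timeout <- t_final > deadline_ms
  is_error <- !is_timeout & !trials$trials$correct
  keep <- !is_timeout & !is_error
  report <- exclusion_report(n_total = length(keep),
                             n_timeout = sum(is_timeout),
                             n_error = sum(is_error),
                             n_retained = sum(keep))
  out <- trials
  out$trials <- trials$trials[keep, , drop = FALSE]
  out$samples <- trials$samples[trials$samples$trial_id %in% out$trials$trial_id, ,
                                drop = FALSE]
  rownames(out$trials) <- rownames(out$samples) <- NULL
  list(trials = out, report = report)
}
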