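# Trajectory-shape statistics: signed maximum deviation, reversal
# classification, x-flips.

#' Signed maximum deviation
#'
#' Perpendicular deviation of the trajectory from the ideal straight line
#' between its first and last sample, signed positive toward the competitor
#' side (the side of the unchosen response in mirrored space). Returns the
#' signed deviation of the sample with the largest absolute deviation, so
#' mirroring a trajectory negates the value. Purely spatial: invariant to any
#' monotone time reparameterization.
#'
#' @param x,y trajectory coordinates in normalized, mirrored space (correct
#'   response at x = +1).
#' @return Signed maximum deviation in normalized units.
#' @export
max_deviation <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("coincident trajectory endpoints")
  # cross product of the unit line direction with each point offset:
  # positive to the left of travel, i.e. toward the competitor at (-1, 1.5)
  d <- (dx * (y - y[1]) - dy * (x - x[1])) / len
  d[which.max(abs(d))]
}

#' Classify a trajectory as a reversal
#'
#' A trajectory counts as a discrete "change of mind" when its signed
#' maximum deviation strictly exceeds the threshold (default 0.9 normalized
#' units); values at or below the threshold are "no reversal".
#'
#' @param md signed maximum deviation.
#' @param threshold classification threshold.
#' @return logical, \code{TRUE} for reversal.
#' @export
classify_reversal <- function(md, threshold = 0.9) {
  stopifnot(is.finite(md))
  md > threshold
}

#' Count x-flips
#'
#' Number of reversals of the direction of travel along the horizontal axis,
#' counting only excursions whose x-displacement exceeds
#' \code{min_excursion} (a guard against sensor jitter).
#'
#' @param x horizontal coordinates.
#' @param min_excursion minimum displacement (normalized units) for a
#'   direction change to count.
#' @return Nonnegative integer flip count.
#' @export
count_x_flips <- function(x, min_excursion = 0.01) {
  n <- length(x)
  if (n < 2) return(0L)
  flips <- 0L
  dir <- 0L
  ext <- x[1]
  for (i in 2:n) {
    if (dir == 0L) {
      if (x[i] - ext > min_excursion) dir <- 1L
      else if (ext - x[i] > min_excursion) dir <- -1L
      ext <- if (dir == 1L) max(ext, x[i]) else if (dir == -1L) min(ext, x[i]) else ext
    } else if (dir == 1L) {
      if (x[i] > ext) ext <- x[i]
      else if (ext - x[i] > min_excursion) { flips <- flips + 1L; dir <- -1L; ext <- x[i] }
    } else {
      if (x[i] < ext) ext <- x[i]
      else if (x[i] - ext > min_excursion) { flips <- flips + 1L; dir <- 1L; ext <- x[i] }
    }
  }
  flips
}

#' Per-trial spatial summaries
#'
#' @param trials a normalized, mirrored \code{trial_set}.
#' @param md_threshold reversal threshold on signed maximum deviation.
#' @param min_excursion x-flip noise guard.
#' @return data.frame with one row per trial: \code{trial_id, participant,
#'   condition, md, reversal, x_flips}.
#' @export
spatial_summaries <- function(trials, md_threshold = 0.9, min_excursion = 0.01) {
  stopifnot(inherits(trials, "trial_set"))
  if (!isTRUE(trials$normalized))
    warning("spatial summaries expect normalized, mirrored trajectories")
  ss <- split(trials$samples, trials$samples$trial_id)
  ids <- trials$trials$trial_id
  md <- vapply(ids, function(id) max_deviation(ss[[id]]$x, ss[[id]]$y), numeric(1))
  flips <- vapply(ids, function(id) count_x_flips(ss[[id]]$x, min_excursion),
                  integer(1))
  data.frame(trial_id = ids,
             participant = trials$trials$participant,
             condition = trials$trials$condition,
             md = md,
             reversal = vapply(md, classify_reversal, logical(1),
                               threshold = md_threshold),
             x_flips = flips,
             row.names = NULL, stringsAsFactors = FALSE)
}
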