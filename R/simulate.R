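# Synthetic trajectory generator.
#
# Two generative regimes reproduce the qualitative signatures the analysis
# is designed to separate:
#   continuous      -- one minimum-jerk reach whose heading is a blend of the
#                      correct and competitor directions, relaxing toward the
#                      correct target as evidence accumulates (graded
#                      competition; single velocity bell, single acceleration
#                      peak + deceleration trough);
#   change_of_mind  -- an aborted minimum-jerk commitment toward the wrong
#                      button overlapped with a corrective minimum-jerk reach
#                      toward the correct one (discrete revision; large
#                      deviation, two positive acceleration phases).

# minimum-jerk progress s(tau) and its derivative, clamped to [0, 1]
min_jerk_s <- function(tau) {
  u <- pmin(pmax(tau, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

min_jerk_sdot <- function(tau) {
  u <- pmin(pmax(tau, 0), 1)
  30 * u^2 * (1 - u)^2
}

# truncated-normal draw (simple rejection; lower bound keeps times positive)
rtnorm1 <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
  stop("truncated normal rejection failed; check distribution parameters")
}

# Continuous-competition path evaluated at times t_ms (mirrored space:
# correct target at geometry$target). Heading h(t) is the normalized blend
# w(t) u_correct + (1 - w(t)) u_competitor with
# w(t) = 1 - cw * exp(-(t - onset)/tau); speed is a minimum-jerk bell.
# The residual endpoint gap left by the curved heading is closed smoothly
# (proportionally to the progress profile) so the reach lands on the target.
path_continuous <- function(t_ms, onset_ms, duration_ms, cw, tau_ms, geom) {
  start <- geom$start
  u_c <- geom$target - start
  u_w <- geom$competitor - start
  len <- sqrt(sum(u_c^2))
  u_c <- u_c / sqrt(sum(u_c^2))
  u_w <- u_w / sqrt(sum(u_w^2))

  # integrate the heading field on a fine internal grid
  h <- 2 # ms
  tt <- seq(onset_ms, onset_ms + duration_ms, by = h)
  if (tt[length(tt)] < onset_ms + duration_ms)
    tt <- c(tt, onset_ms + duration_ms)
  w <- 1 - cw * exp(-(tt - onset_ms) / tau_ms)
  hx <- w * u_c[1] + (1 - w) * u_w[1]
  hy <- w * u_c[2] + (1 - w) * u_w[2]
  hn <- sqrt(hx^2 + hy^2)
  hx <- hx / hn
  hy <- hy / hn
  speed <- min_jerk_sdot((tt - onset_ms) / duration_ms) * len / duration_ms
  dt <- diff(tt)
  # trapezoid integration of velocity
  px <- c(0, cumsum((speed[-length(tt)] * hx[-length(tt)] +
                     speed[-1] * hx[-1]) / 2 * dt))
  py <- c(0, cumsum((speed[-length(tt)] * hy[-length(tt)] +
                     speed[-1] * hy[-1]) / 2 * dt))
  # close the endpoint gap along the progress profile
  gap_x <- (geom$target[1] - start[1]) - px[length(px)]
  gap_y <- (geom$target[2] - start[2]) - py[length(py)]
  s <- min_jerk_s((tt - onset_ms) / duration_ms)
  px <- start[1] + px + s * gap_x
  py <- start[2] + py + s * gap_y

  x <- stats::approx(tt, px, xout = t_ms, rule = 2)$y
  y <- stats::approx(tt, py, xout = t_ms, rule = 2)$y
  x[t_ms < onset_ms] <- start[1]
  y[t_ms < onset_ms] <- start[2]
  cbind(x = x, y = y)
}

# Change-of-mind path: full minimum-jerk commitment toward the competitor
# (duration d1) overlapped, from switch_ms onward, with a corrective
# minimum-jerk displacement from the competitor button to the correct one
# (duration d2). Superposition keeps velocity continuous and guarantees two
# positive acceleration phases.
path_change_of_mind <- function(t_ms, onset_ms, d1, d2, switch_ms, geom) {
  start <- geom$start
  s1 <- min_jerk_s((t_ms - onset_ms) / d1)
  s2 <- min_jerk_s((t_ms - switch_ms) / d2)
  x <- start[1] + s1 * (geom$competitor[1] - start[1]) +
    s2 * (geom$target[1] - geom$competitor[1])
  y <- start[2] + s1 * (geom$competitor[2] - start[2]) +
    s2 * (geom$target[2] - geom$competitor[2])
  cbind(x = x, y = y)
}

#' Simulate a single trial
#'
#' Generates one cursor trajectory in normalized, mirrored space (correct
#' response at x = +1) and returns it as a raw trial, mirrored onto the
#' requested response side. Uses the current RNG state unless \code{seed} is
#' given, so identical seeds give bit-identical trials.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param condition condition label, one of \code{"HF","LF","PW","LS"}.
#' @param regime \code{"continuous"} (graded competition) or
#'   \code{"change_of_mind"} (discrete mid-flight revision).
#' @param geometry a \code{\link{mt_geometry}}.
#' @param correct_side which screen side the \emph{correct} response button
#'   is on (counterbalanced across blocks in the task); the stored raw
#'   samples are mirrored accordingly. The recorded \code{response_side} is
#'   the side the cursor actually ended on (the opposite side for error
#'   trials).
#' @param timeout simulate a trial whose movement ends after the deadline.
#' @param error simulate an incorrect response (reach to the wrong button).
#' @param trial_id,participant identifiers carried into the output.
#' @param seed optional integer; if given, \code{set.seed} is called first.
#' @return A list of class \code{mt_trial} with the trial metadata and a
#'   \code{samples} data.frame (\code{t_ms}, \code{x}, \code{y}).
#' @export
simulate_trial <- function(params, condition, regime = c("continuous", "change_of_mind"),
                           geometry = mt_geometry(), correct_side = "right",
                           timeout = FALSE, error = FALSE,
                           trial_id = "T1", participant = "P1", seed = NULL) {
  regime <- match.arg(regime)
  if (!condition %in% CONDITIONS)
    stop("invalid condition label: ", condition)
  if (!correct_side %in% c("left", "right"))
    stop("correct_side must be 'left' or 'right'")
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)

  onset <- rtnorm1(params$onset_latency_ms[1], params$onset_latency_ms[2], 50)
  dur <- rtnorm1(params$movement_duration_ms[1], params$movement_duration_ms[2], 200)
  if (timeout) {
    # slow trial: movement completes past the deadline
    dur <- params$deadline_ms - onset + stats::runif(1, 100, 400)
  }

  geom <- geometry
  if (error) {
    # incorrect response: the reach goes to the competitor button
    geom <- mt_geometry(start = geometry$start, target = geometry$competitor,
                        competitor = geometry$target,
                        capture_radius = geometry$capture_radius)
  }

  if (regime == "change_of_mind") {
    d1 <- params$commit_frac * dur
    d2 <- params$correction_frac * dur
    switch_ms <- NA_real_
    for (i in 1:100) {
      s <- rtnorm1(params$switch_time_ms[1], params$switch_time_ms[2], 0)
      if (s > onset && s < onset + d1) { switch_ms <- s; break }
    }
    if (is.na(switch_ms))
      stop("degenerate change-of-mind: switch time incompatible with movement window")
    end_ms <- max(onset + d1, switch_ms + d2)
  } else {
    end_ms <- onset + dur
  }

  dt <- 1000 / params$sample_rate_hz
  t_last <- if (timeout) end_ms + dt else min(end_ms + 2 * dt, params$deadline_ms)
  n <- max(2L, floor(t_last / dt) + 1L)
  t_ms <- (seq_len(n) - 1L) * dt
  # sampling-clock jitter ("approximately 70 Hz")
  if (n > 1)
    t_ms[-1] <- t_ms[-1] + stats::runif(n - 1L, -1.5, 1.5)

  pos <- if (regime == "change_of_mind") {
    path_change_of_mind(t_ms, onset, d1, d2, switch_ms, geom)
  } else {
    path_continuous(t_ms, onset, dur, params$competitor_weight,
                    params$evidence_tau_ms, geom)
  }
  if (params$motor_noise_sd > 0) {
    pos[, 1] <- pos[, 1] + stats::rnorm(n, 0, params$motor_noise_sd)
    pos[, 2] <- pos[, 2] + stats::rnorm(n, 0, params$motor_noise_sd)
  }

  x <- pos[, 1]
  if (correct_side == "left") x <- -x
  # the side the cursor actually ended on
  response_side <- if (error) setdiff(c("left", "right"), correct_side) else correct_side

  structure(list(trial_id = trial_id, participant = participant,
                 condition = condition, correct = !error, timeout = timeout,
                 response_side = response_side, rt_ms = end_ms,
                 regime = regime,
                 samples = data.frame(t_ms = t_ms, x = x, y = pos[, 2])),
            class = "mt_trial")
}

# assemble a trial_set container from a list of mt_trial
new_trial_set <- function(trials, normalized = FALSE, design = NULL) {
  meta <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, participant = tr$participant,
               condition = tr$condition, correct = tr$correct,
               timeout = tr$timeout, response_side = tr$response_side,
               rt_ms = tr$rt_ms,
               regime = if (is.null(tr$regime)) NA_character_ else tr$regime,
               stringsAsFactors = FALSE)
  }))
  samples <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, tr$samples, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- rownames(samples) <- NULL
  structure(list(trials = meta, samples = samples, normalized = normalized,
                 design = design),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("trial_set:", nrow(x$trials), "trials,", nrow(x$samples), "samples",
      if (x$normalized) "(normalized, mirrored)" else "(raw)", "\n")
  print(table(x$trials$condition))
  invisible(x)
}

#' Simulate a full experiment
#'
#' Generates \code{n_participants x 4 conditions x trials_per_condition}
#' trials. Pseudoword trials become change-of-mind trials with a
#' participant-specific probability drawn from a Beta distribution whose mean
#' equals the condition's \code{p_reversal}, so some participants produce no
#' reversals at all while others revise often. Timeout and error trials are
#' interleaved at the design's rates (timeout takes precedence).
#'
#' @param design an \code{\link{experiment_design}}.
#' @param geometry an \code{\link{mt_geometry}}.
#' @return A \code{trial_set} of raw (unmirrored) trials.
#' @export
simulate_experiment <- function(design, geometry = mt_geometry()) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  trials <- vector("list", design$n_participants * 4L * design$trials_per_condition)
  k <- 0L
  for (pid in seq_len(design$n_participants)) {
    participant <- sprintf("S%02d", pid)
    # participant-level heterogeneity in change-of-mind propensity: the
    # participant's personal probability is the Beta quantile at their rank,
    # giving a fixed between-subject profile (some participants never revise,
    # others revise on up to half their trials)
    p_rev <- numeric(4)
    names(p_rev) <- CONDITIONS
    for (cc in CONDITIONS) {
      p0 <- design$conditions[[cc]]$p_reversal
      if (p0 <= 0) { p_rev[cc] <- 0; next }
      if (p0 >= 1) { p_rev[cc] <- 1; next }
      q <- stats::qbeta((seq_len(design$n_participants) - 0.5) /
                          design$n_participants,
                        design$reversal_beta[1],
                        design$reversal_beta[1] * (1 - p0) / p0)
      # rescale so the profile mean is exactly p_reversal
      p_rev[cc] <- min(1, q[pid] * p0 / mean(q))
    }
    for (cc in CONDITIONS) {
      par_c <- design$conditions[[cc]]
      for (j in seq_len(design$trials_per_condition)) {
        k <- k + 1L
        timeout <- stats::runif(1) < design$timeout_rate
        error <- !timeout && stats::runif(1) < design$error_rate
        regime <- if (!timeout && !error && stats::runif(1) < p_rev[cc])
          "change_of_mind" else "continuous"
        side <- if (stats::runif(1) < 0.5) "left" else "right"
        trials[[k]] <- simulate_trial(
          par_c, condition = cc, regime = regime, geometry = geometry,
          correct_side = side, timeout = timeout, error = error,
          trial_id = sprintf("%s_%s_%02d", participant, cc, j),
          participant = participant)
      }
    }
  }
  new_trial_set(trials, normalized = FALSE, design = design)
}

#' Write a trial set to disk
#'
#' \code{long_csv} writes one row per cursor sample
#' (\code{trial_id,participant,condition,correct,timeout,t_ms,x,y}) plus a
#' JSON sidecar (\code{<path>.json}) with the generating design for
#' provenance. \code{wide_csv} writes one MouseTracker-style row per trial
#' with the trajectory resampled to 101 time-normalized steps.
#'
#' Numeric fields are serialized with 17 significant digits so a write/read
#' round trip is bit exact.
#'
#' @param trials a \code{trial_set}.
#' @param path output CSV path.
#' @param format \code{"long_csv"} or \code{"wide_csv"}.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(trials, path, format = c("long_csv", "wide_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(trials, "trial_set"))
  if (nrow(trials$trials) == 0) stop("empty trial set")
  num <- function(v) sprintf("%.17g", v)
  if (format == "long_csv") {
    meta <- trials$trials[match(trials$samples$trial_id, trials$trials$trial_id), ]
    df <- data.frame(trial_id = trials$samples$trial_id,
                     participant = meta$participant,
                     condition = meta$condition,
                     correct = meta$correct,
                     timeout = meta$timeout,
                     t_ms = num(trials$samples$t_ms),
                     x = num(trials$samples$x),
                     y = num(trials$samples$y),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- lapply(split(trials$samples, trials$samples$trial_id)[unique(trials$samples$trial_id)],
                   function(s) {
      tt <- seq(min(s$t_ms), max(s$t_ms), length.out = 101)
      c(stats::approx(s$t_ms, s$x, xout = tt)$y,
        stats::approx(s$t_ms, s$y, xout = tt)$y,
        max(s$t_ms) - min(s$t_ms))
    })
    m <- do.call(rbind, rows)
    colnames(m) <- c(paste0("X_", 1:101), paste0("Y_", 1:101), "rt_ms")
    meta <- trials$trials[match(rownames(m), trials$trials$trial_id), ]
    mnum <- matrix(num(m), nrow = nrow(m), dimnames = dimnames(m))
    df <- data.frame(trial_id = rownames(m), participant = meta$participant,
                     condition = meta$condition, correct = meta$correct,
                     timeout = meta$timeout,
                     as.data.frame(mnum, stringsAsFactors = FALSE),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  sidecar <- paste0(path, ".json")
  prov <- list(format = format, n_trials = nrow(trials$trials))
  if (!is.null(trials$design)) {
    d <- trials$design
    prov$design <- list(n_participants = d$n_participants,
                        trials_per_condition = d$trials_per_condition,
                        timeout_rate = d$timeout_rate, error_rate = d$error_rate,
                        reversal_beta = d$reversal_beta, seed = d$seed,
                        conditions = lapply(d$conditions, unclass))
  }
  jsonlite::write_json(prov, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
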