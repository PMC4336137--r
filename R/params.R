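#' Normalized mouse-tracking geometry
#'
#' Trajectories are analysed in the conventional normalized space of
#' two-choice mouse-tracking designs: the start button is at the origin,
#' the correct response button at (1, 1.5) and the competitor (incorrect)
#' button at (-1, 1.5). Trials are mirrored so the correct response always
#' lies at x = +1.
#'
#' @param start numeric length-2, start-button position.
#' @param target numeric length-2, correct response button.
#' @param competitor numeric length-2, incorrect response button.
#' @param capture_radius radius (normalized units) within which the cursor
#'   counts as having reached a button.
#' @return A list of class \code{mt_geometry}.
#' @export
mt_geometry <- function(start = c(0, 0), target = c(1, 1.5),
                        competitor = c(-1, 1.5), capture_radius = 0.1) {
  stopifnot(length(start) == 2, length(target) == 2, length(competitor) == 2,
            capture_radius > 0)
  if (isTRUE(all.equal(start, target)))
    stop("degenerate geometry: start equals target")
  structure(list(start = as.numeric(start), target = as.numeric(target),
                 competitor = as.numeric(competitor),
                 capture_radius = as.numeric(capture_radius)),
            class = "mt_geometry")
}

#' Simulation parameters for one stimulus condition
#'
#' Defines the generative model of a single trial: onset latency and
#' movement duration of a minimum-jerk reach, the strength and time constant
#' of the attraction toward the competitor response, the probability and
#' timing of discrete change-of-mind corrections, and per-sample motor noise.
#'
#' Times are milliseconds post stimulus onset. Distribution parameters are
#' given as \code{c(mean, sd)} of a (truncated) normal. The competitor
#' attraction follows \code{w(t) = 1 - competitor_weight * exp(-t/evidence_tau_ms)},
#' the weight on the correct-response heading, rising toward 1 as evidence
#' accumulates.
#'
#' @param sample_rate_hz cursor sampling rate (Hz).
#' @param deadline_ms response deadline (ms).
#' @param screen_px integer pair, screen resolution (used only on pixel export).
#' @param onset_latency_ms c(mean, sd) of movement onset latency.
#' @param movement_duration_ms c(mean, sd) of movement duration.
#' @param competitor_weight initial attraction toward the wrong response, in [0,1].
#' @param evidence_tau_ms time constant of evidence accumulation (ms).
#' @param p_reversal probability that a trial is a discrete change of mind, in [0,1].
#' @param switch_time_ms c(mean, sd) of the change-of-mind redirection time
#'   (ms post stimulus onset).
#' @param motor_noise_sd per-sample i.i.d. Gaussian positional jitter
#'   (normalized units); the default corresponds to roughly one screen pixel.
#' @param commit_frac duration of the aborted ballistic commitment reach in a
#'   change-of-mind trial, as a fraction of \code{movement_duration_ms}
#'   (commitments are faster than deliberate reaches).
#' @param correction_frac duration of the corrective reach after the switch,
#'   as a fraction of \code{movement_duration_ms}.
#' @param seed integer seed (used when the parameter set drives a simulation
#'   directly).
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(sample_rate_hz = 70,
                       deadline_ms = 2000,
                       screen_px = c(1920L, 1080L),
                       onset_latency_ms = c(200, 30),
                       movement_duration_ms = c(700, 60),
                       competitor_weight = 0.2,
                       evidence_tau_ms = 250,
                       p_reversal = 0,
                       switch_time_ms = c(500, 50),
                       motor_noise_sd = 0.001,
                       commit_frac = 0.55,
                       correction_frac = 0.8,
                       seed = 1L) {
  p <- list(sample_rate_hz = sample_rate_hz, deadline_ms = deadline_ms,
            screen_px = as.integer(screen_px),
            onset_latency_ms = as.numeric(onset_latency_ms),
            movement_duration_ms = as.numeric(movement_duration_ms),
            competitor_weight = competitor_weight,
            evidence_tau_ms = evidence_tau_ms,
            p_reversal = p_reversal,
            switch_time_ms = as.numeric(switch_time_ms),
            motor_noise_sd = motor_noise_sd,
            commit_frac = commit_frac,
            correction_frac = correction_frac,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$sample_rate_hz > 0, p$deadline_ms > 0,
            length(p$screen_px) == 2, all(p$screen_px > 0),
            length(p$onset_latency_ms) == 2, p$onset_latency_ms[1] > 0,
            p$onset_latency_ms[2] >= 0,
            length(p$movement_duration_ms) == 2, p$movement_duration_ms[1] > 0,
            p$evidence_tau_ms > 0,
            length(p$switch_time_ms) == 2, p$switch_time_ms[1] > 0,
            p$motor_noise_sd >= 0,
            p$commit_frac > 0, p$commit_frac <= 1,
            p$correction_frac > 0, p$correction_frac <= 1)
  if (p$competitor_weight < 0 || p$competitor_weight > 1)
    stop("competitor_weight must lie in [0, 1]")
  if (p$p_reversal < 0 || p$p_reversal > 1)
    stop("p_reversal must lie in [0, 1]")
  invisible(p)
}

#' Condition labels
#'
#' The four stimulus conditions of the lexical-decision design: High
#' Frequency words, Low Frequency words, Pseudowords, Letters Strings.
#' @export
CONDITIONS <- c("HF", "LF", "PW", "LS")

#' Experiment design for the synthetic dataset
#'
#' @param conditions named list mapping each of \code{"HF","LF","PW","LS"} to
#'   a \code{\link{sim_params}} object.
#' @param n_participants number of simulated participants.
#' @param trials_per_condition trials per condition per participant.
#' @param timeout_rate fraction of trials exceeding the deadline.
#' @param error_rate fraction of (non-timeout) trials answered incorrectly.
#' @param reversal_beta c(shape1, shape2) of the Beta distribution describing
#'   the between-subject spread in change-of-mind propensity. Each
#'   participant's personal probability is the Beta quantile at their rank
#'   (with shape2 rescaled so the profile mean equals the condition's
#'   \code{p_reversal}), reproducing the reported participant profile: a
#'   couple of participants with no reversals, several with few, some
#'   revising on up to half their trials.
#' @param seed integer seed for the whole experiment.
#' @return A list of class \code{experiment_design}.
#' @export
experiment_design <- function(conditions = default_condition_params(),
                              n_participants = 22,
                              trials_per_condition = 24,
                              timeout_rate = 0.056,
                              error_rate = 0.032,
                              reversal_beta = c(1.2, 4.5),
                              seed = 1L) {
  if (!setequal(names(conditions), CONDITIONS))
    stop("conditions must be a named list with exactly the labels HF, LF, PW, LS")
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            timeout_rate >= 0, timeout_rate < 1,
            error_rate >= 0, error_rate < 1,
            length(reversal_beta) == 2, all(reversal_beta > 0))
  for (p in conditions) validate_sim_params(p)
  structure(list(conditions = conditions[CONDITIONS],
                 n_participants = as.integer(n_participants),
                 trials_per_condition = as.integer(trials_per_condition),
                 timeout_rate = timeout_rate, error_rate = error_rate,
                 reversal_beta = as.numeric(reversal_beta),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Default per-condition simulation parameters
#'
#' Competitor attraction is graded with stimulus uncertainty
#' (LS < HF < LF < PW) and Pseudowords additionally start moving ~100 ms
#' later, so their condition-mean velocity peak lags the other conditions.
#' Only Pseudowords produce change-of-mind trials (p_reversal = 0.21).
#'
#' @param motor_noise_sd positional jitter shared by all conditions.
#' @return Named list of \code{\link{sim_params}}, one per condition.
#' @export
default_condition_params <- function(motor_noise_sd = 0.001) {
  list(
    HF = sim_params(competitor_weight = 0.20, motor_noise_sd = motor_noise_sd),
    LF = sim_params(competitor_weight = 0.45, motor_noise_sd = motor_noise_sd),
    PW = sim_params(competitor_weight = 0.70, motor_noise_sd = motor_noise_sd,
                    onset_latency_ms = c(300, 40), p_reversal = 0.21),
    LS = sim_params(competitor_weight = 0.10, motor_noise_sd = motor_noise_sd)
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("experiment_design:", x$n_participants, "participants x",
      x$trials_per_condition, "trials x 4 conditions =",
      x$n_participants * x$trials_per_condition * 4L, "trials\n")
  cat("  timeout rate", x$timeout_rate, "| error rate", x$error_rate,
      "| seed", x$seed, "\n")
  for (cc in CONDITIONS) {
    p <- x$conditions[[cc]]
    cat(sprintf("  %s: competitor_weight=%.2f onset=%.0f(%.0f)ms p_reversal=%.2f\n",
                cc, p$competitor_weight, p$onset_latency_ms[1],
                p$onset_latency_ms[2], p$p_reversal))
  }
  invisible(x)
}
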