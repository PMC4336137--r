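# End-to-end orchestration: simulate/read -> normalize -> exclude ->
# kinematics -> spatial measures -> condition means -> cross-correlation ->
# group inference -> report bundle.

#' Analysis configuration
#'
#' Collects every analysis constant in one declarative object. The defaults
#' are the standard values of the mouse-tracking lexical-decision analysis:
#' 2000 ms deadline, 13 ms kinematic grid, 50 cross-correlation bins of 39 ms
#' over 1950 ms, velocity windows [400,700) and [600,900) ms, acceleration
#' windows [300,600) and [600,800) ms, reversal windows [300,525), [526,750),
#' [751,975), [976,1275) ms, maximum-deviation threshold 0.9 and an
#' eleven-point onset rule.
#'
#' @param design an \code{\link{experiment_design}} used when \code{input} is
#'   NULL.
#' @param input optional path to a long-format CSV of recorded trials.
#' @param geometry an \code{\link{mt_geometry}} for normalization and target
#'   capture.
#' @param deadline_ms response deadline.
#' @param dt_ms per-trial kinematic grid spacing.
#' @param ccf_bin_ms,ccf_n_bins grid of the condition-mean series used for
#'   cross-correlation.
#' @param ccf_max_lag maximum lag in bins.
#' @param vel_windows,acc_windows lists of half-open windows for the
#'   velocity/acceleration ANOVAs.
#' @param rev_windows list of windows for the reversal-group t-tests.
#' @param best_vel_window,best_acc_window per-trial averaging windows feeding
#'   the Bayesian pairwise comparisons.
#' @param md_threshold reversal threshold on signed maximum deviation.
#' @param onset_run_length increasing-velocity run defining movement onset.
#' @param smooth_passes 3-point moving-average passes applied to per-trial
#'   acceleration before double-peak detection (noise guard).
#' @param prominence_frac peak prominence threshold for double-peak
#'   detection, relative to the profile maximum.
#' @param mcmc \code{\link{best_mcmc}} settings.
#' @param run_bayes run the Bayesian comparisons (they dominate runtime).
#' @param seed master seed for simulation and MCMC.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(design = experiment_design(),
                            input = NULL,
                            geometry = mt_geometry(),
                            deadline_ms = 2000,
                            dt_ms = 13,
                            ccf_bin_ms = 39, ccf_n_bins = 50, ccf_max_lag = 10,
                            vel_windows = list(c(400, 700), c(600, 900)),
                            acc_windows = list(c(300, 600), c(600, 800)),
                            rev_windows = list(c(300, 525), c(526, 750),
                                               c(751, 975), c(976, 1275)),
                            best_vel_window = c(400, 900),
                            best_acc_window = c(300, 800),
                            md_threshold = 0.9,
                            onset_run_length = 11,
                            smooth_passes = 2,
                            prominence_frac = 0.25,
                            mcmc = best_mcmc(),
                            run_bayes = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "analysis_config")
}

condition_pairs <- function() {
  list(c("HF", "LF"), c("HF", "PW"), c("PW", "LS"),
       c("HF", "LS"), c("LF", "LS"), c("LF", "PW"))
}

#' Per-participant reversal proportions
#'
#' @param spatial spatial-summary data.frame (from
#'   \code{\link{spatial_summaries}}), already restricted to the condition of
#'   interest (Pseudowords).
#' @return data.frame: participant, n_reversal, n_total, fraction.
#' @export
per_participant_reversals <- function(spatial) {
  if (nrow(spatial) == 0) stop("no trials supplied")
  agg <- stats::aggregate(reversal ~ participant, data = spatial,
                          FUN = function(v) c(sum(v), length(v)))
  data.frame(participant = agg$participant,
             n_reversal = agg$reversal[, 1],
             n_total = agg$reversal[, 2],
             fraction = agg$reversal[, 1] / agg$reversal[, 2],
             stringsAsFactors = FALSE)
}

# Table-1-style summary of a condition's mean profiles: velocity peak,
# acceleration peak and deceleration peak with times binned into 50 ms
# reporting windows
peak_table_row <- function(cond, mean_vx, mean_ax) {
  win50 <- function(t) sprintf("%d-%d", 50 * (t %/% 50), 50 * (t %/% 50) + 50)
  iv <- which.max(mean_vx$values)
  ia <- which.max(mean_ax$values)
  idd <- which.min(mean_ax$values)
  data.frame(condition = cond,
             vpeak_ms = mean_vx$t_ms[iv], vpeak = mean_vx$values[iv],
             apeak_ms = mean_ax$t_ms[ia], apeak_window = win50(mean_ax$t_ms[ia]),
             apeak = mean_ax$values[ia],
             dpeak_ms = mean_ax$t_ms[idd], dpeak_window = win50(mean_ax$t_ms[idd]),
             dpeak = mean_ax$values[idd],
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either a recorded dataset or a freshly simulated
#' one and returns a report bundle: exclusion accounting, per-trial movement
#' events and spatial summaries, condition-mean profiles with a Table-style
#' peak summary, cross-correlations of all condition pairs (velocity and
#' acceleration), window ANOVAs with Tukey HSD, the Pseudoword
#' reversal/no-reversal analysis (windowed Welch t-tests, per-participant
#' proportions, double-peak rates) and, when \code{run_bayes} is TRUE,
#' Bayesian two-group estimates for all condition pairs and for the reversal
#' contrast. Deterministic given the config seed.
#'
#' @param config an \code{\link{analysis_config}}.
#' @param verbose print stage-by-stage progress with counts.
#' @return list of class \code{report_bundle}.
#' @export
run_pipeline <- function(config = analysis_config(), verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  # --- data ---------------------------------------------------------------
  if (!is.null(config$input)) {
    raw <- read_trials(config$input, "long_csv")
    say("read %d trials from %s", nrow(raw$trials), config$input)
  } else {
    design <- config$design
    design$seed <- config$seed
    raw <- simulate_experiment(design, config$geometry)
    say("simulated %d trials (seed %d)", nrow(raw$trials), config$seed)
  }

  norm <- normalize_trials(raw, config$geometry)
  excl <- apply_exclusions(norm, config$deadline_ms)
  retained <- excl$trials
  say("exclusions: %d timeout, %d error, %d retained",
      excl$report$n_timeout, excl$report$n_error, excl$report$n_retained)

  # --- kinematics ---------------------------------------------------------
  kin <- trial_kinematics(retained, config$dt_ms, config$deadline_ms)
  meta <- retained$trials
  events <- do.call(rbind, lapply(names(kin), function(id) {
    onset <- detect_onset(kin[[id]], config$onset_run_length)
    ev <- if (is.na(onset)) {
      data.frame(onset_ms = NA_real_, movement_time_ms = NA_real_,
                 vpeak_ms = NA_real_, vpeak = NA_real_, apeak_ms = NA_real_,
                 apeak = NA_real_, dpeak_ms = NA_real_, dpeak = NA_real_,
                 vpeak_latency_ms = NA_real_, apeak_latency_ms = NA_real_,
                 dpeak_latency_ms = NA_real_)
    } else {
      detect_peaks(kin[[id]], onset, config$deadline_ms, config$geometry)
    }
    dp <- detect_double_peak(kin[[id]]$a_euclid, kin[[id]]$t_ms,
                             config$prominence_frac, config$smooth_passes)
    cbind(data.frame(trial_id = id, stringsAsFactors = FALSE), ev,
          data.frame(double_peak = dp$double_peak,
                     second_apeak_ms = dp$second_apeak_ms,
                     trough_crosses_zero = dp$trough_crosses_zero))
  }))
  events <- merge(meta[, c("trial_id", "participant", "condition")], events,
                  by = "trial_id", sort = FALSE)
  say("movement events extracted for %d trials (%d without onset)",
      nrow(events), sum(is.na(events$onset_ms)))

  spatial <- spatial_summaries(retained, config$md_threshold)

  # --- condition-mean profiles and cross-correlation ----------------------
  fine_bins <- as.integer(config$deadline_ms %/% config$dt_ms)
  mean_fine <- list()
  for (m in c("vx", "ax")) {
    mean_fine[[m]] <- lapply(CONDITIONS, function(cc)
      condition_mean_series(kin, meta, cc, m, config$dt_ms, fine_bins))
    names(mean_fine[[m]]) <- CONDITIONS
  }
  mean_ccf <- list()
  for (m in c("vx", "ax")) {
    mean_ccf[[m]] <- lapply(CONDITIONS, function(cc)
      condition_mean_series(kin, meta, cc, m, config$ccf_bin_ms, config$ccf_n_bins))
    names(mean_ccf[[m]]) <- CONDITIONS
  }

  peak_table <- do.call(rbind, lapply(CONDITIONS, function(cc)
    peak_table_row(cc, mean_fine$vx[[cc]], mean_fine$ax[[cc]])))

  profile_shape <- do.call(rbind, lapply(CONDITIONS, function(cc) {
    ev <- count_accel_events(mean_fine$ax[[cc]]$values, mean_fine$ax[[cc]]$t_ms,
                             config$prominence_frac)
    data.frame(condition = cc, n_pos_peaks = ev$n_pos_peaks,
               n_neg_troughs = ev$n_neg_troughs, stringsAsFactors = FALSE)
  }))

  ccf_tables <- list()
  for (m in c("vx", "ax")) {
    ccf_tables[[m]] <- do.call(rbind, lapply(condition_pairs(), function(pr) {
      cc <- cross_correlate(mean_ccf[[m]][[pr[1]]], mean_ccf[[m]][[pr[2]]],
                            config$ccf_max_lag)
      data.frame(pair = paste(pr, collapse = "-"), measure = m,
                 r0 = cc$r[cc$lags == 0], best_lag = cc$best_lag,
                 best_r = cc$best_r, stringsAsFactors = FALSE)
    }))
  }
  say("cross-correlations computed for %d condition pairs",
      length(condition_pairs()))

  # --- window ANOVAs ------------------------------------------------------
  anova_tables <- list()
  for (spec in list(list(measure = "vx", windows = config$vel_windows),
                    list(measure = "ax", windows = config$acc_windows))) {
    for (w in spec$windows) {
      wm <- trial_window_means(kin, meta$trial_id, spec$measure, w)
      res <- oneway_anova_tukey(wm, meta$condition)
      key <- sprintf("%s_%d_%d", spec$measure, w[1], w[2])
      anova_tables[[key]] <- c(list(measure = spec$measure, window = w), res)
    }
  }

  # --- Pseudoword reversal analysis ---------------------------------------
  pw_ids <- meta$trial_id[meta$condition == "PW"]
  pw_spatial <- spatial[spatial$condition == "PW", ]
  rev_ids <- pw_spatial$trial_id[pw_spatial$reversal]
  norev_ids <- pw_spatial$trial_id[!pw_spatial$reversal]
  reversal <- list(n_reversal = length(rev_ids), n_no_reversal = length(norev_ids),
                   per_participant = per_participant_reversals(pw_spatial))
  if (length(rev_ids) >= 2 && length(norev_ids) >= 2) {
    reversal$t_tests <- window_t_tests(kin[norev_ids], kin[rev_ids],
                                       config$rev_windows, "a_euclid")
    xf <- function(ids) {
      v <- spatial$x_flips[match(ids, spatial$trial_id)]
      c(mean = mean(v), sd = stats::sd(v))
    }
    reversal$x_flips <- rbind(no_reversal = xf(norev_ids), reversal = xf(rev_ids))
  }
  say("PW reversal split: %d reversal / %d no reversal",
      reversal$n_reversal, reversal$n_no_reversal)

  # --- Bayesian comparisons -----------------------------------------------
  best_tables <- NULL
  if (config$run_bayes) {
    best_tables <- list()
    i <- 0L
    for (spec in list(list(measure = "vx", window = config$best_vel_window,
                           name = "velocity"),
                      list(measure = "ax", window = config$best_acc_window,
                           name = "acceleration"))) {
      rows <- lapply(condition_pairs(), function(pr) {
        i <<- i + 1L
        y1 <- trial_window_means(kin, meta$trial_id[meta$condition == pr[1]],
                                 spec$measure, spec$window)
        y2 <- trial_window_means(kin, meta$trial_id[meta$condition == pr[2]],
                                 spec$measure, spec$window)
        b <- best_two_group(y1, y2, config$mcmc, seed = config$seed + i)
        data.frame(comparison = paste(pr, collapse = "-"),
                   muDiff = b$muDiff, prob_mu_gt0 = b$prob_mu_gt0,
                   sigmaDiff = b$sigmaDiff, prob_sigma_gt0 = b$prob_sigma_gt0,
                   effSz = b$effSz, stringsAsFactors = FALSE)
      })
      best_tables[[spec$name]] <- do.call(rbind, rows)
      say("Bayesian estimation on %s window means done", spec$name)
    }
    if (length(rev_ids) >= 2 && length(norev_ids) >= 2) {
      mean_x <- function(ids) vapply(ids, function(id) mean(kin[[id]]$x), numeric(1))
      mean_acc <- function(ids)
        trial_window_means(kin, ids, "a_euclid", range(unlist(config$rev_windows)))
      bx <- best_two_group(mean_x(norev_ids), mean_x(rev_ids), config$mcmc,
                           seed = config$seed + 101L)
      ba <- best_two_group(mean_acc(norev_ids), mean_acc(rev_ids), config$mcmc,
                           seed = config$seed + 102L)
      best_tables$reversal <- data.frame(
        comparison = c("NoReversal-Reversal x", "NoReversal-Reversal acceleration"),
        muDiff = c(bx$muDiff, ba$muDiff),
        prob_mu_gt0 = c(bx$prob_mu_gt0, ba$prob_mu_gt0),
        sigmaDiff = c(bx$sigmaDiff, ba$sigmaDiff),
        prob_sigma_gt0 = c(bx$prob_sigma_gt0, ba$prob_sigma_gt0),
        effSz = c(bx$effSz, ba$effSz),
        hdi95_mu_lo = c(bx$hdi95_mu[1], ba$hdi95_mu[1]),
        hdi95_mu_hi = c(bx$hdi95_mu[2], ba$hdi95_mu[2]),
        stringsAsFactors = FALSE)
      say("Bayesian estimation on reversal contrast done")
    }
  }

  structure(list(config_seed = config$seed,
                 exclusions = excl$report,
                 events = events,
                 spatial = spatial,
                 peak_table = peak_table,
                 profile_shape = profile_shape,
                 mean_series = mean_ccf,
                 ccf = ccf_tables,
                 anova = anova_tables,
                 reversal = reversal,
                 best = best_tables,
                 n_trials = nrow(raw$trials)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle:", x$n_trials, "trials simulated/read;",
      x$exclusions$n_retained, "retained\n")
  print(x$exclusions)
  cat("PW reversal split:", x$reversal$n_reversal, "reversal /",
      x$reversal$n_no_reversal, "no reversal\n")
  cat("tables: peak_table, profile_shape, ccf ($vx/$ax), anova,",
      if (!is.null(x$best)) "best," else "", "reversal\n")
  invisible(x)
}

#' Write a report bundle to CSV/JSON files
#'
#' Emits one CSV per table plus a JSON summary; rerunning the pipeline with
#' the same config and seed reproduces the files byte for byte.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wcsv <- function(df, name) {
    f <- file.path(dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wcsv(bundle$events, "movement_events.csv")
  wcsv(bundle$spatial, "spatial_summaries.csv")
  wcsv(bundle$peak_table, "peak_table.csv")
  wcsv(bundle$profile_shape, "profile_shape.csv")
  wcsv(bundle$ccf$vx, "ccf_velocity.csv")
  wcsv(bundle$ccf$ax, "ccf_acceleration.csv")
  wcsv(bundle$reversal$per_participant, "per_participant_reversals.csv")
  if (!is.null(bundle$reversal$t_tests))
    wcsv(bundle$reversal$t_tests, "reversal_t_tests.csv")
  anova_df <- do.call(rbind, lapply(names(bundle$anova), function(k) {
    a <- bundle$anova[[k]]
    data.frame(analysis = k, measure = a$measure,
               window_start = a$window[1], window_end = a$window[2],
               F = a$F, df_between = a$df_between, df_within = a$df_within,
               p = a$p, mse = a$mse, stringsAsFactors = FALSE)
  }))
  wcsv(anova_df, "window_anova.csv")
  tukey_df <- do.call(rbind, lapply(names(bundle$anova), function(k)
    cbind(analysis = k, bundle$anova[[k]]$pairwise)))
  wcsv(tukey_df, "window_tukey.csv")
  if (!is.null(bundle$best)) {
    for (nm in names(bundle$best))
      wcsv(bundle$best[[nm]], paste0("best_", nm, ".csv"))
  }
  summary_json <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(seed = bundle$config_seed, n_trials = bundle$n_trials,
         exclusions = unclass(bundle$exclusions),
         pw_reversals = bundle$reversal$n_reversal,
         pw_no_reversals = bundle$reversal$n_no_reversal),
    summary_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, summary_json)
  invisible(files)
}
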