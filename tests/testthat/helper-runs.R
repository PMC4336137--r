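# Shared simulated datasets, built once per test run.

.run_cache <- new.env(parent = emptyenv())

# default full-scale experiment (22 x 4 x 24) with kinematics and summaries
default_run <- function(seed = 42) {
  key <- paste0("run", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  raw <- simulate_experiment(experiment_design(seed = seed))
  norm <- normalize_trials(raw)
  excl <- apply_exclusions(norm, 2000)
  kin <- trial_kinematics(excl$trials, 13, 2000)
  res <- list(raw = raw, retained = excl$trials, report = excl$report,
              meta = excl$trials$trials, kin = kin,
              spatial = spatial_summaries(excl$trials))
  .run_cache[[key]] <- res
  res
}

# small design for fast pipeline-level tests
small_design <- function(seed = 42, n_participants = 6, trials = 8) {
  experiment_design(n_participants = n_participants,
                    trials_per_condition = trials, seed = seed)
}

noise_free_params <- function(...) {
  sim_params(motor_noise_sd = 0, ...)
}
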