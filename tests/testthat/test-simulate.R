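test_that("a trial with no competitor and no noise is a straight reach", {
  tr <- simulate_trial(noise_free_params(competitor_weight = 0), "HF",
                       "continuous", seed = 3)
  expect_lt(abs(max_deviation(tr$samples$x, tr$samples$y)), 1e-9)
  last <- nrow(tr$samples)
  expect_equal(c(tr$samples$x[last], tr$samples$y[last]), c(1, 1.5),
               tolerance = 1e-6)
})

test_that("identical seed and parameters reproduce trials bit for bit", {
  p <- sim_params()
  t1 <- simulate_trial(p, "LF", "continuous", seed = 11)
  t2 <- simulate_trial(p, "LF", "continuous", seed = 11)
  expect_identical(t1$samples, t2$samples)

  d <- small_design(seed = 5)
  s1 <- simulate_experiment(d)
  s2 <- simulate_experiment(d)
  expect_identical(s1, s2)
})

test_that("a change of mind switching at 450 ms crosses the reversal threshold", {
  p <- noise_free_params(switch_time_ms = c(450, 0),
                         onset_latency_ms = c(200, 0),
                         movement_duration_ms = c(700, 0))
  tr <- simulate_trial(p, "PW", "change_of_mind", seed = 4)
  md <- max_deviation(tr$samples$x, tr$samples$y)
  expect_gt(md, 0.9)
  expect_true(classify_reversal(md))
})

test_that("regime signature: change-of-mind trials re-accelerate, continuous do not", {
  for (seed in 1:10) {
    tr <- simulate_trial(noise_free_params(competitor_weight = 0.7,
                                           onset_latency_ms = c(300, 40)),
                         "PW", "continuous", seed = seed)
    k <- differentiate(resample_uniform(tr$samples, 13, 2000), 13)
    expect_false(detect_double_peak(k$a_euclid, k$t_ms)$double_peak)
    expect_equal(detect_double_peak(k$a_euclid, k$t_ms)$n_peaks, 1L)

    tr2 <- simulate_trial(noise_free_params(), "PW", "change_of_mind",
                          seed = seed)
    k2 <- differentiate(resample_uniform(tr2$samples, 13, 2000), 13)
    expect_gte(detect_double_peak(k2$a_euclid, k2$t_ms)$n_peaks, 2L)
  }
})

test_that("trajectories end inside the target region and respect the deadline", {
  geom <- mt_geometry()
  for (seed in 1:8) {
    regime <- if (seed %% 2 == 0) "change_of_mind" else "continuous"
    tr <- simulate_trial(sim_params(), "PW", regime, seed = seed,
                         correct_side = "right")
    last <- tr$samples[nrow(tr$samples), ]
    expect_lt((last$x - geom$target[1])^2 + (last$y - geom$target[2])^2,
              geom$capture_radius^2)
    expect_false(tr$timeout)
    expect_lte(max(tr$samples$t_ms), 2000)
  }
  to <- simulate_trial(sim_params(), "HF", "continuous", timeout = TRUE, seed = 9)
  expect_gt(max(to$samples$t_ms), 2000)
  expect_true(to$timeout)
})

test_that("the default design produces the full factorial trial count", {
  d <- experiment_design()
  expect_equal(d$n_participants * 4L * d$trials_per_condition, 2112L)
  s <- simulate_experiment(small_design(seed = 2, n_participants = 3, trials = 5))
  expect_equal(nrow(s$trials), 3 * 4 * 5)
  expect_equal(unname(table(s$trials$condition)), rep(15L, 4),
               ignore_attr = TRUE)
})

test_that("p_reversal = 0 yields no reversal trajectories at zero noise", {
  conds <- default_condition_params(motor_noise_sd = 0)
  conds$PW$p_reversal <- 0
  s <- simulate_experiment(experiment_design(conditions = conds,
                                             n_participants = 4,
                                             trials_per_condition = 6,
                                             timeout_rate = 0, error_rate = 0,
                                             seed = 8))
  sp <- spatial_summaries(normalize_trials(s))
  expect_false(any(sp$reversal))
})

test_that("invalid simulation inputs are rejected", {
  expect_error(simulate_trial(sim_params(), "XX", "continuous"),
               "invalid condition")
  expect_error(sim_params(competitor_weight = 1.2), "competitor_weight")
  expect_error(sim_params(p_reversal = -0.1), "p_reversal")
  expect_error(experiment_design(conditions = list(A = sim_params())),
               "HF, LF, PW, LS")
  # switch time incompatible with the commitment window
  p <- noise_free_params(switch_time_ms = c(5000, 0))
  expect_error(simulate_trial(p, "PW", "change_of_mind", seed = 1),
               "degenerate change-of-mind")
})

test_that("long CSV round trip is bit exact and wide CSV has one row per trial", {
  s <- simulate_experiment(small_design(seed = 3, n_participants = 2, trials = 2))
  f <- tempfile(fileext = ".csv")
  write_dataset(s, f, "long_csv")
  r <- read_trials(f, "long_csv")
  expect_identical(r$samples$t_ms, s$samples$t_ms)
  expect_identical(r$samples$x, s$samples$x)
  expect_identical(r$samples$y, s$samples$y)
  expect_identical(r$trials$trial_id, s$trials$trial_id)
  expect_identical(r$trials$correct, s$trials$correct)
  expect_identical(r$trials$timeout, s$trials$timeout)
  expect_true(file.exists(paste0(f, ".json")))

  s2 <- simulate_experiment(experiment_design(n_participants = 1,
                                              trials_per_condition = 1,
                                              timeout_rate = 0, error_rate = 0,
                                              seed = 4))
  s2$trials <- s2$trials[1:2, ]
  s2$samples <- s2$samples[s2$samples$trial_id %in% s2$trials$trial_id, ]
  fw <- tempfile(fileext = ".csv")
  write_dataset(s2, fw, "wide_csv")
  expect_equal(nrow(utils::read.csv(fw)), 2L)

  empty <- s
  empty$trials <- empty$trials[0, ]
  expect_error(write_dataset(empty, tempfile(), "long_csv"), "empty")
})
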