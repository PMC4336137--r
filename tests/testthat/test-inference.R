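fast_mcmc <- best_mcmc(chains = 2, iter = 800, warmup = 400)

test_that("identical groups yield a symmetric posterior around zero", {
  set.seed(44)
  y <- stats::rnorm(300)
  b <- best_two_group(y, y, fast_mcmc, seed = 5)
  expect_gte(b$prob_mu_gt0, 0.45)
  expect_lte(b$prob_mu_gt0, 0.55)
  expect_lt(abs(b$muDiff), 0.1)
  # HDI is a proper interval containing the mode
  expect_lt(b$hdi95_mu[1], b$hdi95_mu[2])
  expect_gte(b$muDiff, b$hdi95_mu[1])
  expect_lte(b$muDiff, b$hdi95_mu[2])
})

test_that("swapping the groups negates the estimates", {
  set.seed(45)
  y1 <- stats::rnorm(200, 0.8, 1)
  y2 <- stats::rnorm(200, 0, 1)
  a <- best_two_group(y1, y2, fast_mcmc, seed = 6)
  b <- best_two_group(y2, y1, fast_mcmc, seed = 6)
  expect_lt(abs(a$muDiff + b$muDiff), 0.1)
  expect_lt(abs(a$prob_mu_gt0 - (1 - b$prob_mu_gt0)), 0.05)
  expect_lt(abs(a$effSz + b$effSz), 0.15)
})

test_that("an effect-size-one difference is recovered", {
  set.seed(46)
  y1 <- stats::rnorm(500, 1, 1)
  y2 <- stats::rnorm(500, 0, 1)
  b <- best_two_group(y1, y2, fast_mcmc, seed = 7)
  expect_gt(b$effSz, 0.8)
  expect_lt(b$effSz, 1.2)
  expect_gt(b$prob_mu_gt0, 0.99)
})

test_that("degenerate groups are rejected", {
  expect_error(best_two_group(1, c(1, 2)), "n >= 2")
  expect_error(best_two_group(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("one-way ANOVA and Tukey match hand calculations", {
  # identical data in all groups: F = 0, Tukey p = 1
  v <- rep(c(1, 2, 3), 2)
  g <- rep(c("a", "b"), each = 3)
  r0 <- oneway_anova_tukey(v, g)
  expect_equal(r0$F, 0)
  expect_equal(r0$pairwise$p_adj, 1)
  # {1,2,3} vs {4,5,6}: SSB = 13.5, MSW = 1 -> F = 13.5
  r <- oneway_anova_tukey(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(r$F, 13.5)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 4L)
  expect_equal(r$pairwise$diff, 3)
  # with two groups, F equals the square of the pooled t statistic
  set.seed(8)
  v2 <- stats::rnorm(40)
  g2 <- rep(c("a", "b"), 20)
  r2 <- oneway_anova_tukey(v2, g2)
  t2 <- stats::t.test(v2[g2 == "a"], v2[g2 == "b"], var.equal = TRUE)$statistic
  expect_equal(r2$F, unname(t2)^2, tolerance = 1e-12)
  expect_error(oneway_anova_tukey(1:4, rep("a", 4)), "2 groups")
})

test_that("windowed Welch tests behave correctly on equal and separated groups", {
  mk_kin <- function(vals) {
    t <- seq(0, 1000, 50)
    lapply(vals, function(v)
      data.frame(t_ms = t, a_euclid = v + stats::rnorm(length(t), 0, 1e-6)))
  }
  set.seed(10)
  g <- mk_kin(stats::rnorm(30))
  names(g) <- paste0("t", 1:30)
  r_same <- window_t_tests(g, g, list(c(0, 500)), "a_euclid")
  expect_lt(abs(r_same$t), 1e-6)
  expect_gt(r_same$p, 0.99)

  g1 <- mk_kin(stats::rnorm(50, 1, 0.1)); names(g1) <- paste0("a", 1:50)
  g2 <- mk_kin(stats::rnorm(50, 0, 0.1)); names(g2) <- paste0("b", 1:50)
  r <- window_t_tests(g1, g2, list(c(0, 500), c(500, 1000)), "a_euclid")
  expect_equal(nrow(r), 2L)
  expect_true(all(r$p < 1e-6))

  # Welch df matches the Welch-Satterthwaite formula
  m1 <- sapply(g1, function(k) mean(k$a_euclid[k$t_ms >= 0 & k$t_ms < 500]))
  m2 <- sapply(g2, function(k) mean(k$a_euclid[k$t_ms >= 0 & k$t_ms < 500]))
  v1 <- var(m1) / 50; v2 <- var(m2) / 50
  df_ws <- (v1 + v2)^2 / (v1^2 / 49 + v2^2 / 49)
  expect_equal(r$df[1], df_ws, tolerance = 1e-10)
  expect_error(window_t_tests(list(), g2, list(c(0, 500))), "nonempty")
})
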