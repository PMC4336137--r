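# Group comparison: Bayesian two-group estimation (robust t model via JAGS),
# one-way ANOVA with Tukey HSD, and windowed Welch t-tests.

best_model_string <- "
model {
  for (i in 1:N1) { y1[i] ~ dt(mu[1], tau[1], nu) }
  for (i in 1:N2) { y2[i] ~ dt(mu[2], tau[2], nu) }
  for (j in 1:2) {
    mu[j] ~ dnorm(muM, muP)
    tau[j] <- pow(sigma[j], -2)
    sigma[j] ~ dunif(sigmaLow, sigmaHigh)
  }
  nu <- nuMinusOne + 1
  nuMinusOne ~ dexp(1/29)
}
"

#' MCMC settings for \code{\link{best_two_group}}
#'
#' @param chains number of chains.
#' @param iter posterior draws per chain (after warmup).
#' @param warmup adaptation + burn-in iterations per chain.
#' @return list of settings.
#' @export
best_mcmc <- function(chains = 4, iter = 2500, warmup = 1000) {
  stopifnot(chains >= 2, iter >= 100, warmup >= 100)
  list(chains = as.integer(chains), iter = as.integer(iter),
       warmup = as.integer(warmup))
}

# mode of a sample via kernel density maximum
posterior_mode <- function(x) {
  d <- stats::density(x, n = 2048)
  d$x[which.max(d$y)]
}

# shortest interval containing `prob` posterior mass
hdi <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  w <- xs[(m + 1):n] - xs[1:(n - m)]
  i <- which.min(w)
  c(xs[i], xs[i + m])
}

# split-chain potential scale reduction factor
split_rhat <- function(draws) {
  # draws: iterations x chains
  half <- floor(nrow(draws) / 2)
  sub <- cbind(draws[1:half, , drop = FALSE],
               draws[(nrow(draws) - half + 1):nrow(draws), , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian estimation for two groups
#'
#' Fits the robust two-group model: t likelihood with a normality parameter
#' nu shared across groups, separate means and standard deviations per group,
#' broad data-scaled priors (normal on the means with SD 1000x the pooled SD,
#' uniform on the group SDs over [pooled SD/1000, pooled SD*1000], shifted
#' exponential with mean 30 on nu). Sampling runs in JAGS with fixed
#' per-chain RNG seeds, so results are reproducible given \code{seed}.
#'
#' Reported summaries: posterior modes of the difference of means
#' (\code{muDiff = mu1 - mu2}), difference of standard deviations
#' (\code{sigmaDiff}) and effect size
#' \code{effSz = (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2)/2)}; the posterior
#' probabilities that muDiff and sigmaDiff exceed zero; and the 95% highest
#' density interval of muDiff.
#'
#' @param y1,y2 numeric samples (each n >= 2 with nonzero variance).
#' @param mcmc settings from \code{\link{best_mcmc}}.
#' @param seed integer seed.
#' @param keep_draws keep the posterior draws in the result.
#' @return list of class \code{best_posterior}.
#' @export
best_two_group <- function(y1, y2, mcmc = best_mcmc(), seed = 1L,
                           keep_draws = FALSE) {
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  if (length(y1) < 2 || length(y2) < 2) stop("each group needs n >= 2")
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0)
    stop("zero-variance group: the model is not identifiable")
  pooled_sd <- stats::sd(c(y1, y2))
  data <- list(y1 = y1, y2 = y2, N1 = length(y1), N2 = length(y2),
               muM = mean(c(y1, y2)), muP = 1 / (1000 * pooled_sd)^2,
               sigmaLow = pooled_sd / 1000, sigmaHigh = pooled_sd * 1000)
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(mu = c(mean(y1), mean(y2)),
         sigma = c(max(stats::sd(y1), data$sigmaLow * 2),
                   max(stats::sd(y2), data$sigmaLow * 2)),
         nuMinusOne = 29,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  model <- rjags::jags.model(textConnection(best_model_string), data = data,
                             inits = inits, n.chains = mcmc$chains,
                             n.adapt = max(100L, mcmc$warmup %/% 2),
                             quiet = TRUE)
  stats::update(model, n.iter = mcmc$warmup - mcmc$warmup %/% 2,
                progress.bar = "none")
  samp <- rjags::coda.samples(model, c("mu", "sigma", "nu"),
                              n.iter = mcmc$iter, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  mu1 <- draws[, "mu[1]"]; mu2 <- draws[, "mu[2]"]
  s1 <- draws[, "sigma[1]"]; s2 <- draws[, "sigma[2]"]
  mu_diff <- mu1 - mu2
  sigma_diff <- s1 - s2
  eff_sz <- mu_diff / sqrt((s1^2 + s2^2) / 2)

  rhat <- vapply(c("mu[1]", "mu[2]", "sigma[1]", "sigma[2]", "nu"),
                 function(p) split_rhat(sapply(samp, function(ch) as.matrix(ch)[, p])),
                 numeric(1))
  if (max(rhat) > 1.05)
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f (%s)",
                    max(rhat), names(rhat)[which.max(rhat)]))

  res <- list(muDiff = posterior_mode(mu_diff),
              sigmaDiff = posterior_mode(sigma_diff),
              effSz = posterior_mode(eff_sz),
              prob_mu_gt0 = mean(mu_diff > 0),
              prob_sigma_gt0 = mean(sigma_diff > 0),
              hdi95_mu = hdi(mu_diff, 0.95),
              nu_mode = posterior_mode(draws[, "nu"]),
              rhat = rhat,
              n_samples = length(mu_diff),
              n = c(length(y1), length(y2)),
              seed = as.integer(seed))
  if (keep_draws)
    res$draws <- data.frame(muDiff = mu_diff, sigmaDiff = sigma_diff,
                            effSz = eff_sz)
  structure(res, class = "best_posterior")
}

#' @export
print.best_posterior <- function(x, ...) {
  cat(sprintf("Bayesian two-group estimation (n = %d vs %d, %d draws)\n",
              x$n[1], x$n[2], x$n_samples))
  cat(sprintf("  muDiff    mode %.4g  P(>0) = %.1f%%  95%% HDI [%.4g, %.4g]\n",
              x$muDiff, 100 * x$prob_mu_gt0, x$hdi95_mu[1], x$hdi95_mu[2]))
  cat(sprintf("  sigmaDiff mode %.4g  P(>0) = %.1f%%\n",
              x$sigmaDiff, 100 * x$prob_sigma_gt0))
  cat(sprintf("  effSz     mode %.4g   (max split-Rhat %.3f)\n",
              x$effSz, max(x$rhat)))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD
#'
#' @param values numeric response (e.g. per-trial window means).
#' @param group factor or character grouping (e.g. condition).
#' @return list with \code{F}, \code{df_between}, \code{df_within}, \code{p},
#'   \code{mse} and a \code{pairwise} data.frame (Tukey-adjusted).
#' @export
oneway_anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk),
                         diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  list(F = s[1, "F value"],
       df_between = s[1, "Df"], df_within = s[2, "Df"],
       p = s[1, "Pr(>F)"], mse = s[2, "Mean Sq"],
       pairwise = pairwise)
}

#' Windowed Welch t-tests
#'
#' Two-tailed Welch (unequal-variance) t-test comparing per-trial window
#' means of two groups, one test per window.
#'
#' @param kin1,kin2 named lists of per-trial \code{kinematic_series} for the
#'   two groups.
#' @param windows list of half-open windows \code{c(a_ms, b_ms)}.
#' @param measure series column to average within windows.
#' @return data.frame with one row per window: bounds, t, Welch df, p, and
#'   the two group means.
#' @export
window_t_tests <- function(kin1, kin2, windows, measure = "a_euclid") {
  if (length(kin1) == 0 || length(kin2) == 0) stop("both groups must be nonempty")
  do.call(rbind, lapply(windows, function(w) {
    m1 <- trial_window_means(kin1, names(kin1), measure, w)
    m2 <- trial_window_means(kin2, names(kin2), measure, w)
    tt <- stats::t.test(m1, m2, alternative = "two.sided", var.equal = FALSE)
    data.frame(window_start = w[1], window_end = w[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean1 = mean(m1), mean2 = mean(m2))
  }))
}
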