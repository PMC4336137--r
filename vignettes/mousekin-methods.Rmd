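---
title: "Methods: trajectory generation and kinematic analysis in mousekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory generation and kinematic analysis in mousekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousekin)
```

## Scope

mousekin analyses computer-mouse cursor trajectories from two-choice
decision experiments — the paradigm in which a participant starts a
movement at the bottom of the screen and clicks one of two response
buttons at the top, while the cursor is sampled continuously. The
package covers the full path from raw samples to group-level inference:

1. a **synthetic trajectory generator** whose defaults mimic a
   four-condition lexical-decision experiment (high-frequency words,
   low-frequency words, pseudowords, letter strings);
2. **trajectory I/O and normalization** (long/wide CSV, mirroring into
   the standard analysis space);
3. **kinematic derivation** (uniform resampling, velocity and
   acceleration by central differences, movement-onset and peak
   detection, double-acceleration-peak detection);
4. **spatial measures** (signed maximum deviation, reversal
   classification, x-flips);
5. **time-series comparison** (condition-mean profiles, lagged
   cross-correlation);
6. **group inference** (window ANOVAs with Tukey HSD, Welch t-tests,
   Bayesian two-group estimation with a robust t model);
7. an **end-to-end pipeline** with a declarative configuration and a
   reproducible report bundle.

This vignette documents the generative model, the numerical choices, and
the rationale behind each default, so that results can be interpreted
and the knobs retuned for other designs.

## Coordinate space

All analysis happens in the conventional normalized mouse-tracking
space (`mt_geometry()`): the start button at the origin, the two
response buttons at $(\pm 1,\, 1.5)$, and each trial mirrored so that
its *correct* response lies at $x = +1$. The competitor button is
therefore always at $x = -1$, and "deviation toward the competitor" is
unambiguous in sign across trials. `normalize_trials()` performs the
affine map and the mirroring; for screen-pixel recordings you pass the
pixel geometry (screen-down y axes are handled by the sign of the y
scale). Normalization is idempotent.

A cursor counts as "on a button" when it is within the
`capture_radius` (default 0.1 normalized units) of that button. The
radius stands in for the clickable button area; it is used for the
movement-time measure (time until the cursor enters the correct
button's capture region for good).

## The generative model

### Continuous-competition trials

A trial is a minimum-jerk reach perturbed by graded attraction toward
the competitor. The minimum-jerk profile
$$s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5, \qquad \tau \in [0, 1]$$
is the classic smooth, bell-shaped-velocity primitive of goal-directed
arm movements: velocity is zero at both ends, there is exactly one
acceleration peak followed by one deceleration peak.

Competition is modelled as a time-varying heading blend. At time $t$
after movement onset the instantaneous heading interpolates between the
direction to the competitor and the direction to the correct target
with weight
$$w(t) = 1 - c_w\, e^{-t/\tau_e},$$
where $c_w$ is `competitor_weight` (initial pull toward the wrong
response) and $\tau_e$ is `evidence_tau_ms` (how quickly accumulating
evidence overcomes the pull; default 250 ms). The path is obtained by
integrating this heading along the minimum-jerk speed profile on a
fine (2 ms) grid, then closing the small endpoint gap with a
minimum-jerk-weighted correction so every reach lands exactly on the
target. With $c_w = 0$ the path is exactly straight and the signed
maximum deviation is numerically zero.

This produces the graded-competition signature: larger $c_w$ gives
larger curvature toward the competitor but still a *single*
acceleration/deceleration pair — the condition-mean acceleration keeps
the one-peak/one-trough "butterfly" shape.

### Change-of-mind trials

With probability `p_reversal` a trial is instead a discrete revision:
the participant first commits to the competitor and then corrects.
The trajectory is a superposition of two minimum-jerk components,

* a full commitment reach from the start to the *competitor*, of
  duration `commit_frac` × movement duration (default 0.55 — ballistic
  commitments are faster than deliberate reaches), and
* a corrective displacement (competitor → target) starting at the
  switch time, of duration `correction_frac` × movement duration
  (default 0.8).

Because the two components are superposed rather than concatenated,
velocity is continuous at the switch and the acceleration profile has
**two** positive peaks separated by a trough — the kinematic marker of
a change of mind. The switch time is drawn from a truncated normal
(default mean 500 ms, sd 50 ms post stimulus onset). With the default
geometry virtually all change-of-mind trials exceed the
maximum-deviation threshold of 0.9 (see below), so the spatial and the
kinematic classification agree.

### Trial assembly and the experiment design

Per-sample i.i.d. Gaussian jitter (`motor_noise_sd`, default 0.001
normalized units ≈ one screen pixel) is added to both coordinates, and
the path is sampled at `sample_rate_hz` (default 70 Hz) with ±1.5 ms
timestamp jitter, mimicking a real event stream. Onset latency and
movement duration are truncated-normal per trial (defaults
N(200, 30) ms and N(700, 60) ms).

`experiment_design()` assembles the default synthetic study: 22
participants × 4 conditions × 24 trials = 2112 trials, a 2000 ms
response deadline, 5.6 % timeouts and 3.2 % errors. The per-condition
defaults (`default_condition_params()`) grade the competitor weight
with stimulus uncertainty — LS 0.10 < HF 0.20 < LF 0.45 < PW 0.70 —
and give pseudowords a ~100 ms later movement onset (N(300, 40) ms)
plus `p_reversal = 0.21`; the word and letter-string conditions produce
no discrete reversals.

**Between-subject heterogeneity.** Change-of-mind propensity varies
strongly across people: a couple of participants never revise, several
revise rarely, some revise on up to half their pseudoword trials. The
generator reproduces this with a Beta(1.2, ·) propensity *profile*:
participant $i$ of $n$ gets the Beta quantile at rank $(i - 0.5)/n$,
rescaled so the profile mean equals `p_reversal` exactly. Using fixed
quantiles rather than i.i.d. Beta draws keeps the dataset-level
reversal fraction tight around its nominal value (the i.i.d. version
has a between-dataset sd of ~0.04 at 22 participants) while preserving
the characteristic skewed participant profile. Trial-level assignment
remains random.

**What the generator does and does not emulate.** It reproduces the
qualitative kinematic structure of the paradigm: graded spatial
attraction, delayed pseudoword velocity peaks, single-peaked word
profiles, double-peaked revisions, realistic exclusion rates, sampling
jitter, and participant heterogeneity. It does *not* calibrate
absolute peak amplitudes across conditions (only their ordering by
competition is implied, not enforced), does not model within-trial
pauses or sub-movement segmentation beyond the single correction, and
does not simulate response-button click scatter.

## Kinematic derivation

**Resampling.** Raw samples are piecewise-linearly interpolated onto a
uniform grid, default `dt_ms = 13` ms (the 70 Hz native spacing is
~14.3 ms, so 13 ms slightly oversamples; it also tiles the 39 ms
comparison bins exactly 3:1). Values past the last sample hold the
final position (the cursor rests on the button).

**Differentiation.** Velocity and acceleration use second-order
central differences, with one-sided differences at the boundaries.
Central differences are exact for quadratics at interior points, which
the test suite exploits. Units: positions are normalized units, time
is ms; velocities are reported per second and accelerations per
second², so magnitudes are O(1)–O(10).

**Movement onset.** Onset is the time of the first sample that starts
a run of 11 strictly increasing x-velocity values (`onset_run_length =
11`, i.e. ~140 ms of sustained rise at 13 ms spacing). A long run
makes the rule robust to jitter-induced micro-rises without any
smoothing; a trial with no such run has no onset (`NA`) and is dropped
from event-based summaries.

**Peaks.** `detect_peaks()` reports the velocity peak, the (positive)
acceleration peak, the (negative) deceleration peak, their latencies
from onset, and the movement time — the time at which the cursor
enters the correct button's capture region and stays inside through
the deadline.

**Double-peak detection.** `detect_double_peak()` decides whether an
acceleration profile has two distinct positive peaks separated by a
trough, using topographic prominence: a local maximum counts only if
its prominence is at least `prominence_frac` (default 0.25) of the
global maximum. The relevant trough is the *final sustained
deceleration trough* — the last qualifying negative trough with no
qualifying peak after it; a second positive peak must occur before it.
An optional noise guard applies `smooth_passes` passes of a 3-point
moving average before detection (the pipeline uses 2 passes; at the
default noise level this yields change-of-mind sensitivity 1.0 with a
false-positive rate ≈ 0 on word trials). The detector also reports
whether the inter-peak trough crosses zero (a full deceleration before
re-acceleration) or stays positive (a hesitation).

## Spatial measures

**Signed maximum deviation.** For each trial the perpendicular
deviation of every sample from the straight line first-sample →
last-sample is computed; the reported value is the signed deviation of
the sample with the largest *absolute* deviation. Positive means
toward the competitor side. This convention (the one used by the
mousetrap ecosystem, often written MAD) is mirror-antisymmetric:
reflecting a trajectory about the direct path negates the value.

**Reversal classification.** A trial is a discrete reversal iff its
signed maximum deviation strictly exceeds `md_threshold = 0.9`
normalized units — i.e. the cursor went at least 90 % of the
button-separation half-width toward the *wrong* button before
returning. At 0.9, graded-curvature trials (even at `competitor_weight
= 0.7`) essentially never cross, while committed-then-corrected trials
essentially always do, so the threshold separates the two generative
regimes cleanly.

**x-flips.** The number of sign reversals in horizontal travel
direction, counted on the zigzag sequence of alternating x-extrema;
excursions smaller than `min_excursion = 0.01` are ignored so pixel
jitter does not count. Change-of-mind trials have ≥ 1 flip by
construction; clean reaches have ~0.

## Time-series comparison

**Condition means.** `condition_mean_series()` averages a kinematic
measure over all retained trials of a condition on a common grid —
by default 50 bins of 39 ms (1950 ms ≈ the 2000 ms deadline). 39 ms is
3 × the 13 ms kinematic grid, so per-trial samples map onto comparison
bins without interpolation ambiguity.

**Lagged cross-correlation.** `cross_correlate()` computes
$r(\ell) = \mathrm{cor}(a_t,\, b_{t-\ell})$ for
$\ell = -L, \dots, L$ (default $L = 10$ bins = 390 ms), normalizing
each correlation on the overlapping segment only (local
normalization), which keeps $r(0) = 1$ exact for identical series and
makes $r_{ab}(\ell) = r_{ba}(-\ell)$ hold identically. `best_lag` is
the lag maximizing $r$, with ties resolved toward the smaller $|\ell|$.
If profile $b$ is a delayed copy of $a$ by $j$ bins, `best_lag` is
$-j$: the pseudoword condition, whose velocity peak trails the word
conditions by roughly 100–160 ms, shows up as a 3–5 bin displacement
with near-unity peak correlation.

**Reporting windows.** Window means use half-open intervals
$[t_0, t_1)$ so adjacent windows partition time without double
counting. The pipeline defaults follow common practice for this
paradigm: velocity windows [400, 700) and [600, 900) ms, acceleration
windows [300, 600) and [600, 800) ms, and four reversal-contrast
windows [300, 525), [526, 750), [751, 975), [976, 1275) ms. Peak times
are additionally reported binned into 50 ms windows.

## Group inference

**Window ANOVAs.** For each window, per-trial window means are
compared across the four conditions with a one-way ANOVA
(`stats::aov`) followed by Tukey HSD for all pairwise contrasts. The
analysis unit is the trial; with ~1900 retained trials the F tests are
very well powered, so the Tukey table is the informative output.

**Reversal contrast.** Pseudoword trials are split by the reversal
classification, and per-trial mean absolute acceleration in each
reversal window is compared between groups with Welch t-tests
(`stats::t.test`, unequal variances).

**Bayesian two-group estimation.** `best_two_group()` implements the
standard Bayesian alternative to the t-test: both groups follow a
Student-t likelihood with group means $\mu_1, \mu_2$, group scales
$\sigma_1, \sigma_2$, and a shared normality parameter $\nu$ with a
shifted-exponential prior of mean 30 (values above ~30 are effectively
normal). Priors are deliberately vague: normal on the $\mu$'s with sd
1000 × the pooled data sd, uniform on the $\sigma$'s over [pooled
sd/1000, pooled sd × 1000]. Sampling uses JAGS (4 chains, 2500
iterations after 1000 adaptation/burn-in by default, `best_mcmc()`);
per-chain RNG seeds derived from the user seed make the posterior
reproducible to the draw. Reported quantities are posterior modes
(kernel-density argmax) of $\mu_1 - \mu_2$, $\sigma_1 - \sigma_2$ and
the effect size
$(\mu_1 - \mu_2)/\sqrt{(\sigma_1^2 + \sigma_2^2)/2}$, shortest 95 %
highest-density intervals, and $P(\mu_1 - \mu_2 > 0)$. A split-half
$\widehat R > 1.05$ on any monitored parameter triggers a convergence
warning. In the pipeline the analysis unit is the per-trial window
mean (velocity window [400, 900) ms, acceleration window [300, 800)
ms), for all six condition pairs and for the reversal contrast.

## The pipeline and reproducibility

`analysis_config()` collects every constant above in one object;
`run_pipeline()` executes simulation (or CSV ingest) → normalization →
exclusions → kinematics → events → spatial measures → condition means
→ cross-correlations → ANOVAs → reversal analysis → Bayesian
comparisons, and `write_report()` serializes the result as CSV tables
plus a JSON summary. All numeric CSV output is printed with `%.12g`,
and every random stage (simulation, MCMC) is seeded from the config
seed, so rerunning the pipeline with the same configuration reproduces
the report **byte for byte** — the test suite checks file checksums.

Exclusions follow the standard two-stage rule with disjoint
categories: trials whose final sample exceeds the deadline are
timeouts; of the remainder, incorrect responses are errors; only
correct, within-deadline trials enter the kinematic analyses, and the
counts conserve (`timeouts + errors + retained = total`).

Typical problem sizes: the default 2112-trial experiment simulates in
a few seconds; kinematic derivation for all retained trials takes
about a second; each Bayesian fit takes tens of seconds at the default
MCMC settings, so a full pipeline run with `run_bayes = TRUE` (14
fits) dominates at several minutes. Set `run_bayes = FALSE` or shrink
`best_mcmc()` for exploratory runs.

## Known limitations

* Absolute peak amplitudes across conditions are not calibrated; only
  the competition ordering and the latency structure are.
* The ANOVA/Tukey analyses treat trials as exchangeable units rather
  than modelling participants as random effects; with the generator's
  modest between-subject variance this is conservative enough, but for
  real data a mixed model would be preferable.
* The double-peak detector assumes at most one correction per trial —
  multi-revision trajectories are reported simply as "double peak".
* Wide-format I/O assumes the MouseTracker-style fixed 101-sample
  layout and a uniform within-trial grid.
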