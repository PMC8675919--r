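---
title: "Drift-diffusion analysis of odor detection in background mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-diffusion analysis of odor detection in background mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorddm)
```

## The scientific problem

Animals must detect behaviourally relevant odors ("targets") inside mixtures
of irrelevant ones ("backgrounds"). Adding background odorants makes
detection harder, but *how* the interference acts on the decision process is
not obvious: backgrounds could masquerade as target-like evidence, suppress
the target signal, or inject noise into the decision dynamics. These three
possibilities leave different fingerprints on choice accuracy and on
reaction times, and the drift-diffusion model (DDM) makes those fingerprints
quantitative.

`odorddm` implements the full analysis chain for a two-alternative
odor-detection task: closed-form DDM predictions for the three interference
mechanisms, a stochastic trial simulator, a synthetic generator that
emulates the behavioural experiment end to end, session-level
preprocessing, a chi-square quantile fit of per-condition drift and
diffusion, and posterior-predictive / parameter-recovery diagnostics.

## The model

Within a trial, a decision variable follows

$$\frac{dx}{dt} = A + \xi, \qquad
  \mathrm{E}[\xi(t)\xi(t')] = c^2\,\delta(t-t'),$$

starting from $x(0) = m\theta$ with $|m| < 1$, until it first reaches one of
the absorbing thresholds $\pm\theta$. Reaching $+\theta$ means "report
target present", reaching $-\theta$ "report target absent". Writing
$r = 2A\theta/c^2$, the probability of absorption at $+\theta$ is

$$p = \frac{e^{r} - e^{-rm}}{2\sinh r},$$

and the mean decision time is

$$\mathrm{E}[DT] =
  \frac{\theta\,[\cosh r - m \sinh r - e^{-rm}]}{A \sinh r}.$$

Both have removable singularities at $r = 0$; the package switches to the
limits $p \to (1+m)/2$ and $\mathrm{E}[DT] \to \theta^2(1-m^2)/c^2$ (the
pure-diffusion exit time) when $|r| < 10^{-6}$, so that optimizers may visit
$A \approx 0$ safely.

The parameter derivatives share the factor
$g(r) = e^{-rm}[\cosh r + m\sinh r] - 1$, which vanishes only at $r = 0$
and is positive elsewhere (verified numerically on a sign grid in the test
suite). Hence $\partial p/\partial A > 0$,
$\mathrm{sign}(\partial p/\partial c^2) = -\mathrm{sign}(A)$, and
$\partial\mathrm{E}[DT]/\partial c^2 < 0$ always: extra diffusion noise
*always* speeds decisions up.

## The three interference mechanisms

With baseline drifts $A_{+0} > 0$ (target on) and $A_{-0} < 0$ (target off)
and a nondecreasing background map $f$ with $f(0)=0$ (linear with unit gain
by default):

* **false signal** — $A_i = A_{i0} + f(\#BG)$: $p$ rises with background
  count in *both* trial types (more hits, more false alarms);
* **signal reduction** — $A_i = A_{i0} - f(\#BG)$: $p$ falls in both trial
  types;
* **noise boost** — $c^2 = c_0^2 + f(\#BG)$: $p$ contracts toward the
  stimulus-independent level $(1+m)/2$ from both sides, and the mean
  decision time falls in both trial types.

Because these statements follow from the derivative signs above, they hold
for *any* valid baseline and any monotone $f$ — `prediction_table()` is
tested on randomized baselines, not just the illustrative parameter set
($\theta = 1$, $m = 0$, $A_{+0} = 2$, $A_{-0} = -2.5$, $c_0^2 = 3$, $k = 1$)
used for the reference curves. Only the noise-boost pattern — *less accurate
but faster* with more backgrounds — matches behaviour in which report-present
fractions converge and reaction times shrink as backgrounds are added.
Under signal reduction the target-on drift may turn negative at high
background counts; the formulas permit this and the package allows it ($p$
then falls below the unbiased chance level), since only baselines are
sign-constrained.

## First-passage-time distributions

The chi-square fit needs the *defective* CDF
$F_b(t) = P(\text{absorbed at } b \text{ and } DT \le t)$. After mapping to
a unit-diffusion process on $[0, a]$ ($a = 2\theta/c$, start
$z=(1+m)\theta/c$, drift $v = A/c$), two classical series represent
$F_\mathrm{lower}$:

* a **spectral (large-time) series**, $F(t) = P_0 - \frac{\pi}{a^2}
  e^{-vz}\sum_k \frac{k \sin(k\pi z/a)}{\lambda_k} e^{-\lambda_k t}$ with
  $\lambda_k = (v^2 + k^2\pi^2/a^2)/2$, truncated adaptively from the
  $e^{-\lambda_k t}$ decay;
* a **method-of-images (small-time) series** of Gaussian-tail terms,
  integrated analytically and evaluated in log space so strong drifts
  cannot overflow.

The representation is switched at standardized time $t/a^2 = 0.1$; the two
series agree to better than $10^{-8}$ in their overlap, which the test
suite asserts, and each boundary's total mass reproduces the closed-form
choice probability to $10^{-6}$. Quantiles are obtained by monotone
bisection to an absolute tolerance of $10^{-8}$ s (no closed-form inverse
exists).

## Trial simulation

`simulate_first_passage()` integrates the dynamics by Euler-Maruyama. The
plain scheme has a well-known $O(\sqrt{\Delta t})$ first-passage bias —
effectively the threshold sits $\approx 0.58\,c\sqrt{\Delta t}$ too far
because within-step excursions go undetected. At $\Delta t = 10^{-4}$ s
this shifts choice probabilities by a few $10^{-3}$, which is *not*
negligible against Monte-Carlo noise at $n = 10^5$. The simulator therefore
applies the exact Brownian-bridge crossing test within each step (crossing
probability $e^{-2(\theta - x_0)(\theta - x_1)/(c^2\Delta t)}$ per
boundary), reducing the bias to $O(\Delta t)$; the uniform draw is skipped
whenever the exponent is below $-30$, so the extra cost is small. The
correction can be disabled to expose the raw scheme for step-convergence
checks. The default step is $10^{-4}$ s.

`simulate_trials()` adds the task wrapper: a contaminant ("outlier")
process with probability `outlier_rate` — uniform reaction time on
$[T_{er}, 2.8\,\mathrm{s}]$ and a fair coin between the boundaries — and
omission of trials whose reaction time exceeds the response window, since
only responded trials are analysed.

## The synthetic task generator

`generate_mouse_dataset()` emulates the behavioural experiment trial by
trial:

* **sessions**: 70 per mouse by default, trial counts drawn from
  $N(250, 20^2)$; each session's complexity parameter $b$ is drawn from
  $\{0.5, 0.75, 1\}$ (collection sessions all had $b \ge 0.5$; a flag adds
  lower-$b$ "training" sessions to exercise the filter);
* **mixture size**: $x \in \{1..6\}$ with $P(x) \propto b^x$; a target-on
  mixture of $x$ components carries $x-1$ backgrounds (0-5), a target-off
  mixture $x$ backgrounds (1-6) — which is why the background ranges of the
  18-condition grid differ between trial types;
* **trial type**: drawn with probability from the adaptive rule — one minus
  the report-present fraction among the animal's own last five *responded*
  choices (not the trial labels), 1/2 with no history. The target identity
  (A vs B) is a fair coin, as no schedule is specified for it;
* **responses**: from the DDM at the condition's ground-truth parameters,
  plus the contaminant process (2% by default, a realistic lapse rate);
  the 200 ms odor-line delay is treated as already subtracted, so generated
  reaction times live on the delay-corrected clock from the start.

The default ground truth is the **combined mechanism** — drift magnitude
falling ($|A|$ slope 0.2 per background) and diffusion variance rising
(slope 0.12) — expressed in the fitting convention $\theta = 1/2$ with
baselines $A_{+0} = 1.6$, $A_{-0} = -1.9$, $c^2_0 = 0.6$, $m = 0.1$,
$T_{er} = 0.25$ s. These values were chosen once to give realistic session
accuracies (~75-90% on easy conditions, ~60% on the hardest), mean reaction
times near 0.5 s, and the qualitative signatures of the behavioural data:
report-present fractions converging and reaction times falling with
background count. Pure-mechanism and flat variants exist for discrimination
and negative-control tests.

What the generator does *not* emulate: odorant-identity-specific effects,
reward/timeout learning dynamics, satiety or session-position effects, or
across-trial parameter variability. Passing tests on this synthetic data
therefore demonstrate that the estimator recovers the parameters of the
generating DDM under the task's sampling structure — not that real mice
contain no further structure.

## Preprocessing

`filter_sessions()` excludes sessions with $b < 0.5$ (training) or accuracy
below 70%. `normalize_reaction_times()` removes between-session RT shifts:
each session's reaction times are scaled to the session mean and multiplied
by the grand mean. The grand mean is taken as the *unweighted mean of
session means* by default (so every session's mean lands exactly on the
grand mean); the trial-weighted variant is available via `grand = "trial"`
since either reading of "mean reaction time across all sessions" is
defensible. Normalization preserves within-session rank order and ratios.

## Chi-square quantile fitting

For each of the 18 conditions, correct and error responses are separately
summarized by their reaction-time quantiles (0.1, 0.3, 0.5, 0.7, 0.9),
delimiting 6 bins per response type whose observed counts are the implied
fractions (0.1, 0.2, 0.2, 0.2, 0.2, 0.1) of that type's count — 12 summary
statistics per condition, 216 per mouse. Expected counts come from the
defective CDF (minus $T_{er}$) evaluated at the empirical quantiles, mixed
with a 5% uniform contaminant (the allowance for discarded responses), and
the fit minimizes $\sum (O-E)^2/E$ over bins and conditions.

Numerical and design choices:

* **Normalization of expected counts.** The default scales defective-CDF
  differences by the condition's *total* trial count, so correct and error
  bins jointly sum to $N$ and the observed accuracy enters the objective.
  This is the standard form of the chi-square quantile method. A
  within-response-type renormalization (each type rescaled to its own
  count) is available via `normalization = "within"`, but it discards
  accuracy information entirely — with an unbiased start the correct and
  error RT distributions of this DDM are identical, so under "within" the
  drift's sign (and largely its size) would be unidentifiable. It is kept
  for comparison only.
* **Quantiles** use linear interpolation (R's default type 7); the
  convention is configurable since tools differ.
* **Sparse cells**: a response type with fewer than 12 trials is collapsed
  to 2 bins around its median; with no trials it contributes a single
  zero-observation bin whose expected mass still penalizes parameters that
  predict responses there. This keeps the objective stable at the smallest
  cells the task produces.
* **Small-E guard**: expected counts are floored at $10^{-3}$ inside the
  ratio.
* **Free parameters**: one threshold $\theta'_j$ and drift $A_j$ per
  condition (unit diffusion, boundaries at $0$ and $\theta'$, start
  $m'\theta'$), one shared $m'$ and one shared $T_{er}$ — 38 per mouse.
  Bounds: $\theta' \in [0.05, 10]$, $A \in [-20, 20]$,
  $m' \in [0.05, 0.95]$, $T_{er} \in [0, \min RT)$.
* **Optimizer.** Conditions interact only through $(m', T_{er})$, so the
  38-dimensional problem is solved as a 2-dimensional Nelder-Mead simplex
  over the shared pair, with 18 independent warm-started 2-parameter
  simplex solves (method-of-moments initialization: accuracy sets the
  scaled drift through the logit, the mean RT sets the threshold) nested
  inside. Seeded random restarts of the shared pair (2 by default) guard
  against local minima. This is equivalent to the joint minimization and
  far more robust than a direct 38-dimensional simplex.
* **Rescaling.** Because the threshold is a scaling parameter of the drift
  and of $\sqrt{c^2}$, the unit-diffusion solution is converted exactly to
  drift/diffusion units with the threshold fixed instead:
  $A = A_\mathrm{fit}/\theta_\mathrm{fit}$,
  $c^2 = 1/\theta_\mathrm{fit}^2$, $\theta' = 1$ (i.e. $\theta = 1/2$),
  $m = 2m' - 1$. The identities are exactly invertible
  (`unscale_parameters()`), and both parameterizations give identical
  choice probabilities.

## Model checking and recovery

`posterior_predictive_check()` simulates 1000 responses per condition at
the fitted parameters and tabulates observed vs predicted report-present
fractions and median reaction times with unscaled median absolute
deviations. `parameter_trends()` averages fitted drift and diffusion across
mice by background count, pooling the two target identities by simple
average (the separated view is available from each fit's condition table).
`parameter_recovery_report()` compares fits against a generating ground
truth: bias, RMSE and truth-estimate correlation per parameter class, plus
sign agreement of the background trends, with truth rescaled to the fit's
threshold convention through the model's exact scaling family.

## Problem sizes used in the checks

The test suite runs the closed-form-vs-simulation and distribution
agreements at $n = 10^5$ trials per parameter set, mechanism predictions on
100 randomized baselines, and full parameter recovery on one synthetic
mouse with 900 trials per condition (about 16,000 trials — the scale of one
real animal's dataset); the end-to-end behavioural signatures use a
full-scale 70-session generated mouse. One full 38-parameter fit takes on the order of
a minute. These sizes make sampling error small against the effects being
checked while keeping a complete run comfortably fast.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- task_config(n_sessions = 20)
trials <- generate_mouse_dataset(cfg)
kept <- normalize_reaction_times(filter_sessions(trials)$trials)
res <- fit_mouse(kept, seed = 1)
parameter_recovery_report(default_ground_truth(), res$fit)$metrics
posterior_predictive_check(res$fit, kept)
```

## Known limitations

* The model has no across-trial variability in drift, start point or
  non-decision time; misfit from such variability in real data will load
  onto the per-condition parameters.
* All backgrounds are treated as interchangeable — identity-specific
  background potency is outside this analysis.
* The contaminant distribution is declared (uniform on
  $[T_{er}, \text{window}]$) rather than estimated, and the 5% allowance is
  fixed during fitting.
* Euler simulation with bridge correction still carries an $O(\Delta t)$
  bias; at the default step this is far below the statistical resolution of
  any check in the package, but extremely fine tails should use the
  analytic CDF instead.
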