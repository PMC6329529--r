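---
title: "Models and methods for Pavlovian bias in the orthogonalized Go-NoGo task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Pavlovian bias in the orthogonalized Go-NoGo task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the behavioural model

The orthogonalized Go-NoGo task presents four abstract stimuli, one per
condition - Go-to-Win (G2W), NoGo-to-Win (NG2W), Go-to-Avoid-Loss (G2AL) and
NoGo-to-Avoid-Loss (NG2AL) - for 36 trials each in fully randomized order
(144 trials per session).  The correct decision (press or withhold) earns
the better of two outcomes with probability 0.8: +1 versus 0 in the win
conditions, 0 versus -1 in the avoid-loss conditions.  Because the correct
action is orthogonal to outcome valence, the design separates instrumental
learning from the *Pavlovian* tendency to act under the prospect of reward
and to hold still under the prospect of loss.

`gngbias` models a session with a Rescorla-Wagner learner.  Action values
`Q(a, s)` and stimulus values `V(s)` start at zero and are updated on every
responded trial,

    Q <- Q + lambda_v * (rho_v * r - Q)
    V <- V + lambda_v * (rho_v * r - V)

where `r` is the outcome in monetary units (-1, 0, +1), `rho_v` the
*motivational exchange rate* converting outcomes into subjective value (it
doubles as an inverse softmax temperature), and `lambda_v` a learning rate.
The subscript `v` marks parameters that may differ between win and
avoid-loss trials.  `V` is updated on every responded trial regardless of
the action taken: the state-value recursion conditions only on the stimulus,
and we follow that reading rather than gating it by the action.  Action
propensities add two biases to the Go action only,

    q_go   = Q(go, s) + b_go + b_pav * V(s)
    q_nogo = Q(nogo, s)

so `b_go` is a valence-independent action bias and `b_pav`, the *Pavlovian
bias*, couples the propensity to act to the stimulus's current value -
promoting action for appetitive stimuli and suppressing it for aversive
ones.  Choice probabilities pass the propensities through a softmax mixed
with a lapse rate `xi` (irreducible noise):

    p(go) = (1 - xi) * softmax(q)_go + xi / 2

The softmax is computed with max-subtraction so extreme propensities cannot
overflow.

Six variants are registered (`gng_models()`): *valenced learning* (one
`rho`, two learning rates), *valenced sensitivity* (two `rho`s, one
learning rate), and *sensitivity ratio* (appetitive `rho` plus the
log-ratio `kappa = log(rho_av) - log(rho_app)`), each optionally with
*forgetting* - unexperienced state-action values decay toward zero by a
retention fraction `m` per trial.  Per individual, the sensitivity-ratio
model is an exact reparameterization of valenced sensitivity; the two
differ only in where the population prior is placed.  Whether `V` of unseen
stimuli also decays in forgetting models is a documented toggle
(`decay_v`), off by default: the forgetting account is explicit about `Q`
only, and we chose the narrower reading.

Parameters are fitted in a transformed space where a Gaussian population
prior is natural: `log` for strictly positive parameters (`rho`s, `b_pav`),
`logit` for unit-interval parameters (`lambda`s, `xi`, `m`), identity for
`b_go` and `kappa`.

# Hierarchical fitting

`fit_em()` implements type-2 maximum likelihood: independent Gaussian
priors over the transformed parameters describe each wave's population, and
their means and variances are estimated by expectation-maximization, each
wave fitted independently.

Two E-steps are available.  The default (`estep = "mc"`) draws `n_samples`
(default 2000) parameter vectors per subject from the current prior - the
draws are fixed per subject across iterations, so the EM map is
deterministic given the seed and Monte-Carlo errors are independent across
subjects - and computes importance-weighted posterior means and second
moments; the M-step matches the prior to these moments.  The classical
Laplace variant (`estep = "map"`) optimizes each subject's log-posterior
(multi-start BFGS) and updates the prior variance with the MAP variance
plus the mean inverse-Hessian diagonal.  We made the Monte-Carlo E-step the
default after observing, in simulation, that the Laplace variant drifts the
population means of weakly identified log-space parameters upward: the MAP
of a log-parameter with a flat lower likelihood tail sits at the prior
mean, while noise bumps on the upper side pull estimates up, and the
iteration amplifies the asymmetry.  The Monte-Carlo E-step integrates over
the skewed posterior instead and recovers simulated population means to
within about 0.1 in transformed space at n = 150-300.  After convergence
(largest change in any transformed prior mean below `tol = 1e-3`, default
cap 200 iterations), each subject's MAP estimate and Laplace curvature are
computed once at the fitted prior for reporting, and the per-subject
integrated likelihood

    iL = log Integral p(data | theta) N(theta; mu, Sigma) d theta

is estimated by log-mean-exp over the prior draws with a delta-method
standard error.  Group-level model comparison uses

    iBIC = -2 * sum(iL) + N_par * log(n_tr * n_pt)

with `N_par` counting a mean *and* a variance per subject-level parameter,
`n_tr = 144` and `n_pt` the number of participants.  Prior variances are
floored at `1e-6` to prevent collapse.

Numerical safeguards: singular Hessians fall back to diagonal
approximations capped at ten times the prior variance; importance-sampling
effective sample sizes are recorded per subject (`$subjects$ess`); the EM
trace logs the objective per iteration, and the Laplace variant warns if
its monotonicity diagnostic is violated.

# Out-of-sample comparison by left-out likelihoods

`lol_compare()` implements the predictive test: a seeded shuffle splits the
cohort into a group-training set (default 300) and a test set; the training
set yields each model's population prior; then, per test subject, a
random-walk Metropolis sampler (default 4 chains of 2000 retained draws
after 1000 adaptive warmup steps, proposal scaled toward 30 percent
acceptance) targets the posterior over transformed parameters given the
*included* trials only.  The held-out trials - by default the 48th and 96th
(1-based, session-global) - are handled in the *informed* way: their
realized actions and outcomes drive the value recursion, but their
log-probabilities are excluded from the posterior target, so they never
inform parameter estimation.  The left-out likelihood is the log of the
posterior-averaged probability of the held-out actions (the posterior-mean
alternative can be derived from the stored subject draws).  Models are
compared by paired per-subject differences; the summary reports the median
difference in per-trial prediction probability `Ppt = exp(LOL / n_held_out)`
with a bootstrap confidence interval (default 10000 resamples), excluding
subjects whose split-chain scale-reduction diagnostic exceeds 1.1.  Chains
for different models reuse identical per-subject seeds, so a model compared
with itself gives exactly zero paired differences, and between-model
comparisons benefit from common random numbers.

`protected_exceedance()` provides the complementary random-effects view: a
variational Dirichlet model of per-subject model evidences, exceedance
probabilities by Monte-Carlo, and protection through the Bayesian omnibus
risk (`PXP = (1 - BOR) * XP + BOR / K`).

## The informed-versus-agnostic audit

Because learning makes every trial's likelihood depend on the history,
informed handling could in principle bias out-of-sample estimates.
`run_bias_experiment()` audits this with two-armed toy learners:
Rescorla-Wagner with a softmax whose known parameter `tau = 0.1`
*multiplies* action values (the bare-bones analogue of the exchange rate in
the task models), deterministic returns of 1 and 5, 28-trial epochs with
the first 8 hidden, and 10000 epochs per true learning rate (0.05, 0.15,
0.25).  Per epoch the procedure computes, over a grid of 101 learning
rates on [0.005, 0.505], the hidden-trial predictive likelihood under a
flat prior with the visible-trial likelihood either *informed* (hidden
actions fill the gaps) or *agnostic* (the hidden action sequence is
marginalized - exact here, because with deterministic returns the hidden
state reduces to applied-update counts, enumerable by dynamic programming),
plus grid-ML learning-rate estimates under each handling and from the
hidden trials alone.  Eta-greedy learners (exploration rate `eta = 0.1`,
ties split evenly) and an observation-violating variant - exploratory
actions update values only on better-than-expected prediction errors - are
included; note that with positive deterministic returns and zero initial
values every prediction error is non-negative, so the violating rule is
inert under the default returns and the variant coincides with the plain
eta-greedy learner.  One caveat this audit makes explicit: the agnostic
estimate is the exact conditional predictive under the grid prior, so it
weakly dominates any alternative in expected log score; "no bias" should be
read as "differences far below the scale of scientific interest" (the
package's acceptance checks use 0.45 percent of the grand mean prediction
probability as that scale).

# Descriptive and longitudinal analyses

`performance_summary()` scores each condition's trials by occurrence order.
The *early* phase weights position `k` by `max(0, (19 - k) / 18)` - a ramp
falling linearly to zero at the middle of the condition's 36 trials,
anchored to within-condition position; the *late* phase averages positions
19-36.  Missing responses keep their position in the ramp but are excluded
from numerator and denominator.  The descriptive Pavlovian-bias index is
the congruency interaction `((G2W - NG2W) + (NG2AL - G2AL)) / 2`.
Between-wave and between-condition contrasts are medians of within-subject
differences (not differences of medians - the two are computed identically
here and the choice is documented rather than silent) with Wilcoxon
signed-rank tests, Bonferroni-corrected by 4 (condition changes) or 8
(cross-condition contrasts).

`retest_statistics()` reports Pearson correlations for approximately
Gaussian measures and Spearman for skewed ones (defaults: Spearman for
natural-scale `b_pav`, learning rates, lapse rates; Pearson otherwise;
override per measure via `method`).  `gaussianize()` maps values through
average ranks over `n + 1` - the offset keeps the empirical CDF off the
unit boundary - and the inverse Gaussian CDF with the input's mean and SD.
`fit_lcs()` fits the just-identified univariate latent change score model
by direct bivariate-normal maximum likelihood; because the model is
just-identified this is exactly equivalent to the SEM formulation while
avoiding a structural-equation dependency, and the two nested comparisons
(self-feedback fixed at -1, i.e. pure regression to the mean; equal mean
and variance across waves) are likelihood-ratio tests with 1 and 2 degrees
of freedom.  `cluster_fit_values()` fits full-covariance Gaussian mixtures
(via mclust's deterministic model-based hierarchical initialization, with a
small covariance regularization handled by the backend) to the joint
distribution of per-subject integrated likelihoods at two waves and selects
the number of components by BIC.

# The synthetic cohort generator

`population_spec()` defines agents by independent Gaussians over the
transformed parameters.  Defaults are anchored to printed population
summaries of the large longitudinal study this package is built around
wherever those exist: median Pavlovian bias 0.205 (log-mean -1.585), Go
bias 0.73, lapse rate 0.069 (logit-mean -2.60), and a motivational exchange
rate of 5 chosen so that the simulated cohort reproduces the study's median
per-subject integrated likelihood of about -68.9 nats (prediction
probability per trial near 0.62) under the generative prior.  Where nothing
is printed we fixed values once at magnitudes typical of hierarchical fits
of this task family: learning-rate logit means -1.82/-1.59 (appetitive
slightly slower than aversive), and transformed-space SDs of 0.5 (`rho`),
1.0 (learning rates), 0.7 (`b_go`), 0.9 (`b_pav`) and 0.8 (`xi`).  Waves
are simulated with per-agent randomized schedules and pre-drawn 0.8
feedback validity; a second wave applies an additive drift to transformed
means only (spread changes are deliberately out of scope of the default
drift model).  Two robustness families replace the log-normal population of
`b_pav` by a gamma or a normal with matching natural-space moments, the
latter admitting a small negative tail, for checking that fitting under
the log-normal assumption still ranks individuals correctly.

What the generator does *not* emulate: attrition and retest selection,
within-session non-stationarity other than learning itself, response-time
structure, and realistic covariate dependence (covariates, if needed, are
plain Gaussian columns).  Passing recovery and model-selection checks on
these cohorts therefore demonstrates the estimator's correctness under the
model's own assumptions, not robustness to everything real data can do.

# Problem sizes and reproducibility

The shipped checks use sizes chosen to exercise the claims at meaningful
scale: the hidden-trial audit runs its full 10000 epochs; parameter
recovery uses 300 agents with 144 trials each; the model-selection check
uses a 150-agent cohort with a 100-agent training split, 2 chains and 1000
retained draws per test subject - a deliberately scaled-down version of
the full 400/300 design whose conclusions are directional (which model wins
the median paired difference), not magnitude-sensitive.  Every stochastic
stage derives its seed deterministically from a single master seed, so all
results in the README and the acceptance script are exactly reproducible.

# Known limitations

* The population mean of the lapse rate is the one quantity the hierarchical
  estimator does not pin down tightly at 144 trials per agent: in
  simulation its logit-scale estimate settles roughly 0.1-0.15 below the
  cohort's generative mean, with a correspondingly inflated population SD,
  because occasional lapses trade off against low outcome sensitivity at
  the individual level.  The remaining population means recover to within
  about 0.1.  This persists as the Monte-Carlo sample grows, so it is a
  property of the maximum-likelihood estimate under these conditions, not
  of the sampler.

* The MAT-file containers of the original deposit are not readable here;
  deposited data must be exported to the long CSV layout first, and the
  two deposited-data checks stay red without it.
* The per-agent recovery correlation of the Pavlovian bias depends on the
  scale it is computed on and on the assumed population spread, for which
  the study prints no value.  Under our defaults the natural-scale Pearson
  correlation exceeds 0.8 (the shipped checks compute it), but it is
  dominated by the well-identified upper tail of the skewed bias
  distribution; log-scale and rank correlations are noticeably lower,
  because agents with near-zero biases are intrinsically unidentifiable
  from 144 trials and shrink to the prior.  Recovery claims should name
  their scale.
* The grid-based audit reproduces the magnitude (about 0.03-0.04 log
  units) but not the printed direction of the difference between informed
  and agnostic ML learning-rate estimates; see the discussion above of why
  an exact agnostic marginal cannot be beaten in expected log score.
* Population priors are diagonal; correlated population structure is out
  of scope.
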