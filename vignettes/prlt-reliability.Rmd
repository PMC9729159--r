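---
title: "Models, estimation and reliability in prlrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimation and reliability in prlrel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlrel)
```

# The task and what is being measured

`prlrel` analyses two-session probabilistic reversal learning task (PRLT)
studies. In the task a participant repeatedly chooses between two stimuli
whose win probabilities are 80% and 20%, perfectly anti-correlated. After an
acquisition phase the contingencies reverse five times (after trials 55, 70,
90, 105 and 125 of 160), so accurate performance requires flexible
re-learning. Feedback is drawn independently on every trial by comparing a
uniform draw against the chosen option's win probability, so the realized
win rate varies around the nominal contingencies across people and sessions.
We code rewards as +1 (win) and −1 (loss); the learning models below are
scale-free up to their sensitivity parameters, and the symmetric coding is
what makes the counterfactual update for the unchosen option exactly the
mirrored outcome −r.

The scientific question the package is built around is *reliability*: if
the same people perform the task twice, how stable are the readouts — both
the raw behavioral metrics (accuracy, stay–switch behavior, perseveration,
reaction times) and the parameters of reinforcement-learning models fitted
to the choices — and, crucially, how strongly does the answer depend on how
those readouts are estimated?

# The model space

Two families of Q-learning models are crossed with three update rules and
win/loss-specific parameterizations, giving 12 models per family
(`enumerate_models()`):

* **Softmax family.** Values are updated by
  \(Q_{a,t+1} = Q_{a,t} + \alpha\,(r - Q_{a,t})\) and mapped to choice
  probabilities through a softmax with inverse temperature \(\beta\).
  Learning rates and temperatures can be split by the valence of the
  (previous) feedback: \(\alpha_{win}/\alpha_{loss}\),
  \(\beta_{win}/\beta_{loss}\).
* **Reinforcement-sensitivity family.** The softmax slope is fixed at 1 and
  the reward is scaled inside the update,
  \(Q_{a,t+1} = Q_{a,t} + \alpha\,(\rho r - Q_{a,t})\): because
  \(|Q| \le \rho\), the sensitivity \(\rho\) bounds the value difference and
  thereby carries choice stochasticity. \(\rho\) can likewise be split into
  \(\rho_{win}/\rho_{loss}\).

Update rules: **SU** leaves the unchosen option untouched; **DU** exploits
the anti-correlated task structure and updates the unchosen option toward
the mirrored outcome \(-r^{*}\); a third variant attenuates that
counterfactual update by a weight \(\kappa \in (0,1)\), which combines
multiplicatively with whichever learning rate applies on that trial.

Numerical conventions worth stating explicitly:

* Q-values start at (0, 0) — the symmetric, uninformative initialization —
  and are reset at the start of every session.
* The softmax is computed in the max-subtracted overflow-safe form, and
  choice probabilities are floored at 1e−12 inside the log.
* On the first trial of a session a two-\(\beta\) (or two-\(\rho\)) model
  has no previous feedback to select the win/loss parameter; we use the win
  parameter by convention (configurable via `first_trial`; it affects 1 of
  160 trials).
* Parameter transforms: learning rates and \(\kappa\) are inverse-logit
  transformed to (0,1); a single \(\beta\) or \(\rho\) is
  exponential-transformed to be positive; win/loss-specific \(\rho\) pairs
  are estimated in native space, so the fitting layer tolerates negative
  proposals for them. We also exponential-transform win/loss-specific
  \(\beta\) pairs: positivity is intrinsic to an inverse temperature, and
  the native-space convention is specific to the dual-sensitivity models.

# Estimation regimes

All fitting happens in unconstrained space with BFGS and numerical
gradients, restarted from random points (`n_restarts`, default 10) with an
outer best-of-`n_repeats` wrapper (default 10); both are scale factors that
can be reduced for exploratory runs. Per-subject Hessians are computed by
central finite differences (step 1e−4), symmetrized, and jittered by
1e−6·I (escalating tenfold) if not positive definite.

* **ML** maximizes the per-subject likelihood alone. With only 160 trials
  per session, near-deterministic subjects push \(\beta\) (and parameters
  correlated with it) along a flat likelihood ridge, producing huge
  estimates — the root cause of ML's poor test-retest reliability.
* **MAP0** adds an independent Gaussian prior with mean 0 and variance 10
  on every unconstrained parameter — weak regularization that caps the
  ridge excursions.
* **EM-MAP** learns a *multivariate empirical* Gaussian prior from the
  cohort by expectation maximization: the E-step computes per-subject MAP
  estimates under the current prior together with a Laplace approximation
  of their posterior covariance (inverse Hessian); the M-step sets the
  prior mean to the average MAP estimate and the full prior covariance to
  the across-subject second moment *plus* the average Laplace covariance,
  so the prior reflects both the spread of the point estimates and their
  uncertainty. Iteration stops when the penalized group log-likelihood
  changes by less than `tol`. The prior covariance diagonal is floored at
  1e−6 to avoid collapse on degenerate cohorts.

Sessions can be fitted **separately** or **jointly**. Joint fitting
concatenates both sessions with separate per-session parameters and a value
reset at the boundary; for ML and MAP0 the joint objective factorizes, so
joint and separate estimates coincide (a property the tests pin). For
EM-MAP the joint prior spans both sessions' parameters, so cross-session
covariances inform every subject's estimates — this partial pooling across
sessions is what drives the reliability gains the package demonstrates.

**Model selection** uses the integrated BIC: the group marginal likelihood
with subject parameters integrated out under the empirical prior,
penalized by the number of free prior parameters
(\(d + d(d+1)/2\) for a full covariance; a diagonal count is available)
times \(\log\) of the total number of choices. The integral is estimated by
Monte-Carlo sampling from the prior, K = 2000 draws by default, shared
across subjects. This choice is robust to multimodality and cheap at these
dimensions, but the Monte-Carlo error of the total at K = 2000 is a few
iBIC units on a ~40-subject cohort (the stability test documents a ±10
band); differences between models on this task are an order of magnitude
larger, so rankings are unaffected. Raise `K` if two models ever land
within MC error of each other.

# Behavioral metrics and their hierarchical estimation

`compute_raw_metrics()` produces per subject-session proportions and means:
accuracy is the fraction of choices of the currently better option
*regardless of realized feedback*; stay probabilities condition on the
previous trial's feedback; perseveration uses the strictest literal reading
of "choosing the same incorrect stimulus after two consecutive losses" —
the previous two trials must be the same option, incorrect both times, with
loss feedback both times, and the event is repeating that option. Empty
conditioning sets yield `NA`, never 0/0. Reaction-time summaries use only
trials with a recorded RT. No post-reversal trials are excluded.

`fit_hierarchical_metric()` re-estimates each metric with lme4:
binary metrics as binomial models aggregated to subject-session counts
(likelihood-identical to trial-level Bernoulli fits, but much faster),
reaction times as Gaussian trial-level models. Joint mode uses
`~ 1 + (1 | subject/session)`; the win–loss RT difference adds a
previous-feedback factor with random slopes,
`rt ~ prev_win + (1 + prev_win | subject/session)`. When a maximal
structure fails to converge the function falls back to a documented simpler
structure with a warning. The returned predicted values are the shrunken
response-scale predictions; their variance components feed the
*model-calculated* ICC(1), defined — following the convention this package
replicates — as
\(\sigma^2_{subject} / (\sigma^2_{subject} + \sigma^2_{session(subject)})\),
i.e. without the residual term. A conventional variant including the
residual is available via `include_residual = TRUE` in
`icc_from_variance_components()`; it answers a different question (expected
agreement of single *observations* rather than of session-level true
scores) and is not the default.

# The reliability toolbox

`icc_a1()` implements the two-way, single-measure, absolute-agreement
ICC — the appropriate coefficient when time is a design factor with one
observation per subject and time point — and `icc_1()` the one-way
random-effects ICC. Confidence intervals use the standard F-distribution
constructions for these designs at 95%. Both functions flag zero-variance
inputs as undefined rather than returning 0/0. Spearman–Brown correction
\(r_{SB} = 2r/(1+r)\) projects split-half correlations to full length;
`classify_icc()` applies the Cicchetti clinical-significance bins with
half-open intervals ([.40, .60), [.60, .75), [.75, 1]) to resolve the
gaps in the quoted rule. For joint EM fits,
`pearson_from_prior_cov()` turns the prior covariance between a parameter's
two session copies into a model-calculated correlation that incorporates
estimation uncertainty. `variance_partition()` decomposes subject × session
matrices into between-subject, session and error components via the
two-way mean squares (method-of-moments, truncated at zero).

# The synthetic-data generator

`population_spec()`/`generate_study()` emulate the study design: 38–40
subjects × 2 sessions × 160 trials, counterbalanced task versions
(subject 1 plays A then B, subject 2 B then A, alternating), per-subject
parameters drawn from a multivariate Gaussian over both sessions'
unconstrained parameters with a configurable cross-session correlation.
The shipped default population uses the `DU-2rho-alpha` model with
unconstrained means (3, 2, 0) and SDs (1, 1, 0.8) and cross-session
r = 0.7 — fixture constants chosen so that simulated cohort accuracy lands
near 0.8, the healthy-adult range; they are generator settings, not
empirical claims. Reaction times come from a purely descriptive process
(the choice models carry no RT likelihood): subject intercept
(mean 700 ms, SD 100 ms), a −22 ms shift after win feedback, trial noise
(SD 150 ms), truncated to (150, 1500] ms.

What the generator deliberately does **not** emulate: response omissions,
dropout, practice effects beyond an optional mean shift, RT–choice
coupling, and any drift of parameters within a session. Tests passing on
this generator therefore demonstrate the estimation and reliability
machinery under a correctly specified model; they cannot certify behavior
under the misspecification real data bring.

# Simulation experiments and what the tests assert

`recover_reliability()` reproduces the recoverability-of-reliability
design: per dataset, 38 normally distributed subject indices correlated at
a known r across sessions generate 160 Bernoulli trials (binary,
choice-like; index = success probability, clipped to [0.01, 0.99] after
correlation induction) or Gaussian trials (continuous, RT-like). The
marginal index distributions are generator choices: binary mean 0.7,
SD 0.1; continuous mean 700, SD 100, trial noise SD 250. Four estimation
routes are compared to the truth: per-session means, separate hierarchical
models, the joint hierarchical model, and the model-calculated ICC from the
joint model's variance components. The acceptance suite asserts the
qualitative pattern at 100 datasets: means and separate models
underestimate high true reliabilities (attenuation by trial noise), the
joint model's predicted values overestimate them (sessions share a subject
intercept), and the model-calculated route is the most accurate. For
continuous data the means-route attenuation has the closed form
\(r \cdot \sigma^2_{index} / (\sigma^2_{index} + \sigma^2_{noise}/n)\),
which the suite checks to ±0.03.

`parameter_recovery()` and `model_recovery()` probe the estimation layer:
EM-MAP recovery correlations exceed ML's for every `DU-2rho-alpha`
parameter at study scale, and iBIC prefers a simple generating model over a
five-parameter alternative. `posterior_predictive_check()` closes the loop
from fitted parameters back to behavior; generated metrics correlate with
observed ones but with less variance (shrinkage).

Problem sizes in the shipped test-suite runs are the package's desk-scale
choices: 20 replicate cohorts of 38 subjects for the estimation-regime
ordering (with `n_restarts` 2–3, one repeat, EM capped at 20–40
iterations, tolerance 0.02), 100 datasets for the binary recovery pattern,
200 for the attenuation check, 10 for parameter recovery. Full-replication
scales (500 datasets, 10 restarts, 10 repeats) are the documented function
defaults.

# Design choices that were genuinely open

* **Perseveration window.** The one-line field definition leaves the
  conditioning open; we pin the strictest literal reading (same incorrect
  option, two consecutive losses on it) and freeze it with a hand-counted
  fixture.
* **Chance-level exclusion.** A subject is excluded only when a two-sided
  binomial test (α = .05) cannot reject chance accuracy *and* the subject
  deviates > 3 SD from the remaining cohort — both halves of the published
  rule, with test level and sidedness made explicit.
* **EM M-step moments.** The uncertainty-inclusive covariance update
  (scatter of MAP estimates plus mean Laplace covariance) is the standard
  empirical-Bayes construction and matches the description of
  model-calculated variances as "point-estimate variance plus mean squared
  standard error"; toolboxes differ in details we cannot observe, so this
  is documented as our construction rather than asserted as identical.
* **iBIC integration.** Monte-Carlo prior sampling rather than a Laplace
  approximation (robust to multimodal subject posteriors, trivially cheap
  in ≤ 10 dimensions); prior parameter count for a full covariance, with a
  diagonal option.
* **Optimizer.** Quasi-Newton with numerical gradients; reliabilities are
  insensitive to supplying analytic gradients on this problem, so the
  simpler optimizer is preferred.

# Known limitations

* ML estimates are *expected* to diverge for near-deterministic subjects;
  they are reported as-is (flagged, finite through the transform) because
  that instability is part of the phenomenon under study.
* The model-calculated ICC convention omits residual variance by design
  (see above); with very few trials per session the two conventions
  diverge substantially.
* The iBIC is Monte-Carlo noisy at the unit scale; compare models, not
  digits.
* glmer/lmer convergence failures on extreme simulated datasets are
  handled by fallback structures or dataset exclusion (always counted and
  reported), which can bias simulation summaries if failures are frequent;
  at the shipped settings they are rare.
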