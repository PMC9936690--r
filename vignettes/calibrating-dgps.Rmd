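---
title: "Calibrating data-generating processes by iterative bisection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating data-generating processes by iterative bisection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The calibration problem

A Monte Carlo simulation study stands or falls with its data-generating
process (DGP). Investigators usually know which *characteristics* the
simulated data should have — "outcome prevalence 10%", "treatment relative
risk 0.80", "model c-statistic 0.80", "marginal hazard ratio 0.80" — but
the DGP is parameterised by regression coefficients, and the map from
coefficients to characteristics has no closed form once covariates are
involved. The marginal relative risk induced by a treatment log-odds ratio,
for example, depends on the whole covariate distribution.

Each characteristic handled here is, however, monotone (in expectation) in
one natural scalar parameter:

| characteristic | summary | calibrated parameter |
|---|---|---|
| outcome (or treatment) prevalence | $\frac{1}{N}\sum_i Y_i$ | logistic intercept $\beta_0$ |
| marginal relative risk | $E[Y(1)]/E[Y(0)]$ | treatment log-odds ratio $\gamma$ |
| marginal risk difference | $E[Y(1)-Y(0)]$ | treatment log-odds ratio $\gamma$ |
| model c-statistic | $\Pr(\text{case score} > \text{control score})$ | coefficient scale $\sigma$ |
| marginal hazard ratio | pooled-arms Cox coefficient, exponentiated | conditional log-hazard ratio $\gamma$ |

Monotonicity turns calibration into stochastic root finding, and the
simplest robust root finder is bisection: start from an interval
$(\theta^{lower}, \theta^{upper})$ whose endpoint summaries straddle the
target, evaluate the summary at the midpoint by re-simulating outcomes,
keep the half-interval that still straddles the target, repeat. After $K$
iterations the interval width is $1/2^K$ of the initial width, so a
$(-10, 10)$ bracket pins the parameter to about $0.02$ within 10
iterations and to about $0.001$ within 15.

## The super-population

All evaluators work on one large simulated cohort (default
$N = 10^6$; `covariate_spec()`), big enough that empirical summaries
approximate population quantities: the Monte Carlo standard error of a
prevalence near 0.10 is about $3\times10^{-4}$, of a relative risk near
0.8 about $3\times10^{-3}$, of a c-statistic near 0.8 under $10^{-3}$, and
of a marginal log hazard ratio about $1.4\times10^{-3}$. The default
covariate block is five independent standard-normal and five independent
Bernoulli(0.5) columns; `generate_superpopulation()` accepts a
caller-supplied column generator, because nothing in the bisection
machinery depends on the covariate distribution.

The covariates are drawn **once** per calibration run and frozen; only the
outcomes are re-simulated at each midpoint. This removes covariate noise
from the evaluator, so iteration-to-iteration variation reflects outcome
sampling alone.

## The four ready-made scenarios

`default_scenarios()` returns runnable configurations; all use covariate
log-odds (or log-hazard) ratios $\log 1.25, \log 1.5, \log 1.75, \log 2,
\log 2.5$ repeated over both covariate blocks, and the treatment-selection
model uses $\log 1.1, \log 2, \log 3, \log 1.5, \log 1.5$ twice over.

**Prevalence.** Outcomes follow
$\operatorname{logit} \Pr(Y_i = 1) = \beta_0 + \sum_j \beta_j X_{ij}$, and
$\beta_0$ is bisected over $(-10, 10)$ until the empirical prevalence hits
the target (0.10 by default). The same recipe calibrates the
treatment-selection intercept to a treatment prevalence (0.20 by default).

**Relative risk / risk difference.** The outcome model gains a treatment
term, $\beta_0 + \gamma Z_i + \sum_j \beta_j X_{ij}$, with $\beta_0$
pre-calibrated so that the prevalence *if no one were treated* is on
target. Both potential outcomes are then simulated for every subject — set
$Z \equiv 0$ to draw $Y(0)$, set $Z \equiv 1$ to draw $Y(1)$ — and
$\gamma$ is bisected until $E[Y(1)]/E[Y(0)]$ (or $E[Y(1) - Y(0)]$) reaches
its target. Because a logistic $\gamma$ is a conditional odds ratio, not a
relative risk, the calibrated $\gamma$ has no closed form; under the
default DGP a marginal relative risk of 0.80 needs $\gamma \approx -0.300$
(odds ratio 0.741).

**c-statistic.** The outcome model becomes
$\beta_0 + \sigma \sum_j \beta_j X_{ij}$: one global scale multiplies every
covariate coefficient, preserving all their ratios, and is bisected over
$(0, 10)$. At each midpoint the package fits a logistic model to the
simulated sample by maximum likelihood and computes the c-statistic of the
*fitted* scores — the quantity a study would report. A `fitted_scores =
FALSE` fast mode scores with the true linear predictor instead, which at
$N = 10^6$ is indistinguishable in practice but skips the fit. Note that
$\sigma$ scales only the covariate sum, never $\beta_0$, so moving
$\sigma$ shifts the prevalence; calibrating both at once is what
`sequential_calibrate()` is for.

**Marginal hazard ratio.** Event times follow a proportional-hazards model
$\log h_i(t) = \log h_0(t) + \gamma Z_i + \sum_j \beta_j X_{ij}$ and are
generated by inverting the cumulative hazard:
$T = \bigl(-\log U / (\lambda e^{LP})\bigr)^{1/\nu}$ for a Weibull
baseline $h_0(t) = \lambda \nu t^{\nu-1}$ (exponential when $\nu = 1$).
Both potential times $T(0), T(1)$ are generated, the $2N$ records are
concatenated with an arm indicator, and a univariate Cox model on the arm
indicator estimates the marginal hazard ratio. The hazard ratio is
non-collapsible: with nonzero covariate effects the marginal effect is
attenuated toward the null relative to the conditional $\gamma$, and under
the default covariate effects the attenuation factor is roughly one half —
a marginal hazard ratio of 0.80 requires a conditional log-hazard ratio of
about $-0.46$, i.e. a conditional hazard ratio near 0.63.

With no censoring the Cox partial likelihood depends on the pooled event
times only through their ordering, and the inverse-hazard transform is
monotone, so the marginal-HR evaluator is *exactly* invariant to
$\lambda$ and $\nu$ (a property the test suite asserts to $10^{-10}$).
The default baseline is exponential with $\lambda = 1$; the calibrated
$\gamma$ is well defined regardless of that choice.

*A caution on effect scales.* Everywhere in this package the conditional
treatment effect is specified on the **log** scale (`treatment_log_or`,
`treatment_log_hr`), and trace tables print the parameter on that scale.
Calibration tables produced by other software sometimes print the
multiplier ($e^\gamma$) instead; the two are easy to confuse and produce
very different marginal effects (bisecting the multiplier scale makes the
fitted marginal HR behave like $\sqrt{\text{multiplier}}$ under these
covariate effects). When reproducing external results, check which scale
the printed parameter is on by recomputing one or two trace rows.

## Sequential calibration of interacting parameters

When two characteristics must hold simultaneously — prevalence 0.10 *and*
c-statistic 0.80 — the two parameters interact: changing $\sigma$ moves
the prevalence. `sequential_calibrate()` cycles through the problems,
bisecting each parameter with the others frozen, and repeats the sweep
until a joint re-evaluation at the final parameter set puts every summary
within its tolerance (or `outer_max` sweeps elapse). The joint flag is
deliberately based on that final re-evaluation, not on mid-sweep
summaries, because a later problem's calibration can undo an earlier
one's. The `"joint"` scenario starts the sweep at the outcome model's own
intercept and scale (not at bracket midpoints), so the first intercept
pass sees the unscaled model.

## Stopping rule, tolerances and seeding

Bisection needs a stopping rule; the engine uses a dual criterion — stop
at the first midpoint whose summary is within `tolerance` of the target,
or after `max_iterations`, whichever comes first — and records both in the
result. The default `bisection_settings()` uses `tolerance = 0.001` and
`max_iterations = 25`. A tolerance should be a small multiple of the
summary's Monte Carlo standard error at the chosen $N$: much tighter and
the stop may never trigger (the summary noise floor), much looser and the
parameter inherits slack through the summary-vs-parameter slope. At
$N = 10^6$, 0.001 is 3–4 standard errors for a prevalence and about one
for a hazard ratio, which is why the hazard-ratio acceptance run uses
0.002.

Each evaluation draws outcomes from an independent, deterministically
derived substream (base seed plus iteration index), so a run is exactly
reproducible — identical config and seed give byte-identical trace files —
while evaluations stay independent. The alternative
`common_random_numbers = TRUE` mode reuses one fixed uniform panel for
every evaluation, making the empirical summary a deterministic monotone
function of the parameter; this removes the risk that sampling noise flips
a halving decision near convergence, at the cost of conditioning the
calibrated value on one outcome draw.

Two further randomness conventions are deliberate. Potential outcomes
$Y(0), Y(1)$ (and $T(0), T(1)$) use independent draws per arm by default —
the estimands are functionals of the two marginal distributions, so arm
coupling is irrelevant to the limit — with a shared-uniform option that
couples the arms elementwise (useful for exact algebraic checks such as
$T(1) = T(0)e^{-\gamma}$ under a shared panel). And endpoint verification
of the initial bracket is on by default but can be disabled
(`check_endpoints = FALSE`) when the bracket is known to straddle, since
each endpoint costs a full-size simulation.

## Numerical choices

The logistic fit is iteratively reweighted least squares with step-halving
on the log-likelihood, score-based convergence ($\max_j |X^\top(y-\mu)|_j
\le 10^{-6}$), an overflow-safe log-likelihood, and divergence detection
(coefficients beyond $\pm 30$ flag separation). The univariate Cox fit
maximizes the Breslow partial likelihood by safeguarded Newton iteration
on per-unique-time sufficient statistics; its score tolerance widens with
the event count ($10^{-11}$ per event) because the score is a sum whose
attainable precision scales with $N$, and coefficients beyond $\pm 20$
flag a monotone likelihood (one group's events all first). Simulated times
are continuous so ties have probability zero, but the Breslow path is
exercised by the tests on tied data against an established implementation.
The c-statistic is computed from midranks in $O(N \log N)$, which counts
ties one-half and is invariant to strictly increasing score transforms.
Exact-hit midpoints (summary equal to the target) stop the bisection,
since no halving direction is defined; decreasing evaluators are handled
by negating comparisons, never the recorded summaries.

## What the tests do and do not show

The test suite checks the building blocks against independent oracles
(pairwise enumeration for the c-statistic, grid maximization of the
explicit partial likelihood for the Cox fit, `glm` for the logistic fit,
closed-form 2×2 and quantile identities) and reproduces the reference
calibration results for all four scenarios on a $10^6$-subject
super-population; property checks (interval halving, containment,
monotonicity, null effects, attenuation, rank invariance) run at
$10^4$–$10^5$ subjects to keep the default test run fast. Those sizes are
the package's own choices: large enough that 4-standard-error bounds are
meaningful, small enough that the whole suite runs in about a minute
ahead of the full-size acceptance checks.

Passing tests show that the machinery calibrates *this* family of DGPs —
independent normal/Bernoulli covariates, correctly specified logistic or
proportional-hazards outcomes, no censoring, no missingness. They do not
show that a tolerance appropriate at $N = 10^6$ is appropriate at your
$N$, nor anything about misspecified outcome models, correlated
covariates, or censored event times. The generator hook accepts other
covariate distributions, but the shipped defaults have been exercised only
as described.

## Known limitations

- Only coordinate-wise sequential calibration is provided; there is no
  simultaneous multidimensional root finder, and no derivative-based or
  stochastic-approximation (Robbins–Monro) alternative.
- The relative-risk denominator $E[Y(0)]$ must be positive; calibrating
  vanishingly rare outcomes needs a larger super-population.
- No censoring is generated; the Cox fitter accepts censoring indicators
  so it is reusable, but calibration recipes always pass complete event
  data, and marginal-HR calibration under administrative censoring is out
  of scope.
- A stochastic evaluator can still flip a halving decision when the true
  summary at a midpoint sits within the noise floor of the target; the
  common-random-numbers mode exists precisely for users who prefer a
  deterministic search path.
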