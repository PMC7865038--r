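---
title: "Crowd wisdom, the crowd within, and expertise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowd wisdom, the crowd within, and expertise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crowdwise` analyses judgment-aggregation experiments of the numerosity-estimation
kind: people briefly see a display of 50–100 stars and type how many they think
they saw, ten times per set size. Averaging several estimates — across people
(the *outer crowd*) or across repetitions within one person (the *inner
crowd*) — usually beats a single estimate. This vignette lays out the models
the package implements, the choices behind them, and what its synthetic data
can and cannot tell you about real experiments.

## The bias / MSE / variance decomposition

For estimates $x_1,\dots,x_n$ of a true value $v$, with errors
$e_i = x_i - v$:

* **bias** $=(\bar e)^2$ — squared distance from the crowd mean to the truth,
  the error of the crowd's aggregate;
* **MSE** $=\frac1n\sum e_i^2$ — the error of an average individual estimate;
* **variance** $=\frac1n\sum (e_i-\bar e)^2$ — the diversity of the estimates.

The diversity prediction theorem is the algebraic identity
$\text{variance} = \text{MSE} - \text{bias}$: what a crowd gains over its
average member (*crowd wisdom*, MSE − bias) is exactly the diversity of its
estimates. A crowd of accurate but near-identical estimates has almost
nothing to gain from averaging. `decompose_crowd()` computes the triple and
`verify_dpt()` its residual, which must vanish to floating-point tolerance
(the test suite checks $|{\rm var} - ({\rm MSE}-{\rm bias})| \le
10^{-9}\max(1,{\rm MSE})$ over $10^4$ randomized crowds spanning magnitudes
$10^{-6}$–$10^6$). The divide-by-$n$ (population) variance convention is
forced: the identity is false under divide-by-$(n-1)$.

```{r}
library(crowdwise)
fx <- two_crowds_fixture()
decompose_crowd(fx$crowd_a, fx$truth)
decompose_crowd(fx$crowd_b, fx$truth)
```

## Error scale and cleaning

Accuracy is measured as **squared proportional error**: an estimate of 55
for 50 stars errs by $+0.10$, 45 by $-0.10$, both contributing $0.01$ to
MSE$_P$. The proportional scale makes errors comparable across set sizes.
Responses are deliberately *not* log-transformed; the package follows the
convention of analysing raw proportions so that strongly and weakly skewed
datasets are treated identically.

Estimates at least one order of magnitude off (ratio to the true count
$\ge 10$ or $\le 0.1$, boundaries inclusive — 500 for 50 stars sits exactly
on the boundary and is removed) are treated as typos, quarantined to a
separate table, and excluded. The rule depends only on the ratio, and is
idempotent. Nothing is imputed: a filtered trial simply shortens its series.

## Crowd construction

* **Inner crowds**: one series per participant × set size, in chronological
  order; element $t$ of the aggregation curve is the running mean of the
  first $t$ estimates.
* **Outer crowds**: every participant anchors exactly one crowd and is
  joined by `crowd_size − 1` companions drawn without replacement from the
  other participants (with $n$ crowds of 10 drawn from $n$ people,
  membership across crowds necessarily overlaps). Only each member's
  chronologically first estimate of each set size enters. The member order
  is random but fixed within a crowd and shared across its set sizes, so the
  six aggregation curves of one crowd describe the same people in the same
  order. Whether companions should be drawn with or without replacement is
  not dictated by the aggregation logic; without-replacement was chosen so a
  crowd never contains the same person twice.

The curve observation at $(t)$ is
$\mathrm{MSE}_P(t) = ((\bar x_{1:t} - s)/s)^2$ with $s$ the set size.
Averaging raw estimates and then converting to proportional error is
identical to averaging proportional errors at fixed set size; a test asserts
this equivalence.

## The parabolic crowd-wisdom model

If estimates within an aggregation unit were i.i.d. with variance $V$ and
squared bias $B$ (proportional scale), the expected squared error of the
$t$-mean would be exactly $V/t + B$. The package therefore fits

$$\mathrm{MSE}_P(t) = \frac{a}{t} + b,$$

where $a$ estimates the unit's response variance — the aggregation gain,
i.e. crowd wisdom — and $b$ the asymptotic bias that no amount of averaging
removes. Fitting is hierarchical and Bayesian:

* Population-level $a, b \ge 0$ with **half-normal(0, 0.5)** priors
  (scale = SD of the underlying normal; density at zero
  $2/(0.5\sqrt{2\pi}) \approx 1.596$). Bounded priors are required because
  negative variance or bias is uninterpretable.
* Each unit (participant or outer crowd), and each set size nested within
  unit, carries multiplicative log-normal deviations on both parameters:
  $a_{is} = a\,e^{u_i + v_{is}}$. The log scale keeps every unit-level curve
  nonnegative, which additive deviations would not. Deviation SDs get the
  same half-normal(0, 0.5) prior.
* Observation model: Gaussian noise on the msep values with estimated
  residual scale $\sigma$ (half-normal(0, 0.5) prior); a gamma likelihood
  (mean-parameterised, estimated shape) is available for users who prefer a
  strictly positive observation model, at the cost of rejecting exact-zero
  observations.

Sampling is Gibbs/slice via JAGS. Two numerical choices deserve note:

* **Identification.** Multiplicative deviations leave only the product
  $a\,e^{\bar u}$ identified — the sampler can trade the population
  parameter off against the common level of the deviations. The package
  therefore reports the identified quantity
  $a_{\rm pop} = a\,e^{\overline{u} + \overline{v}}$ (the geometric-mean
  unit-level parameter), computed draw-by-draw from monitored deviation
  means. Doing the equivalent sum-to-zero centring inside the sampler costs
  roughly two orders of magnitude in runtime, because every deviation update
  then touches the whole graph. One interpretive consequence: with skewed
  unit-level parameters the geometric mean sits below the arithmetic mean,
  so population estimates are "typical-unit" rather than "average-unit"
  values.
* **Residual floor.** $\sigma$ is truncated below at 5% of the SD of the
  msep observations. Without the floor, data whose aggregation curves are
  exactly flat (possible when every repetition of an estimate is identical —
  the trained regime below) drive $\sigma \to 0$ and the chains down an
  improper $1/\sigma^N$ spike. The floor binds only when the true residual
  is below 5% of the total msep variation, i.e. for data much cleaner than
  any behavioral experiment produces, and is invisible elsewhere.

Convergence is gated at split-$\hat R \le 1.01$ on the parameters inference
uses — $a$, $b$ and the residual parameter — with a hard error (class
`crowdwise_convergence_error`) otherwise; `retries` windows of doubling
length treat rejected windows as burn-in. Group-deviation SDs are reported
in the diagnostics but not gated: variance components near zero mix slowly
in any Gibbs sampler (the classical funnel) without disturbing the
population-level posterior, and gating on them would reject fits whose
inferential quantities are fully converged. Fits with a single distinct $t$
abort with an identifiability error: $a$ and $b$ enter only through
$a/t + b$, so one $t$ value determines only their sum.

## Savage-Dickey Bayes factors

Evidence that $a$ (or $b$) differs from zero uses the Savage-Dickey density
ratio for nested models:
$\mathrm{BF}_{10} = p(0)/p(0 \mid \text{data})$, prior over posterior
density at the null value. The prior density at zero is analytic. The
posterior density at zero must respect the boundary: a plain kernel
estimator halves the density at the support edge and would double every
BF$_{10}$. The package estimates it by **spline log-density estimation**:
the draws are histogrammed over $[0, \max]$, a Poisson generalized additive
model is fit to the bin counts, and the fitted rate at zero is converted to
a density. Smoothing on the log scale keeps Gaussian-like shapes low-order
polynomials, so the estimator stays accurate where a reflected kernel does
not — reflection creates a cusp in the log-density at zero whenever the
posterior mode sits away from the boundary, and any symmetric kernel
smooths that cusp upward, biasing BF$_{10}$ downward (against a conjugate
truncated-normal oracle the reflected kernel missed by 8–20% where the
spline estimator stays within a few percent). The reflected
Sheather–Jones kernel remains as a fallback should the spline fit fail.
Feeding the estimator draws from the prior itself returns
BF$_{10} = 1$ within about 2% at $10^5$ draws; the suite checks the band
$[0.85, 1.18]$ there, and checks the conjugate truncated-normal toy
model — whose Savage-Dickey ratio is available in closed form — to within
10%. When the posterior leaves the estimated zero-density below $10^{-6}$
times the prior density, BF$_{10}$ is reported as the finite cap $10^6$
rather than infinity (and never below $10^{-6}$). BF$_{10} \ge 3$ is
flagged "alternative", $\le 0.33$ "null", otherwise "inconclusive".

## The synthetic-data generator

`simulate_experiment()` emulates the study design: each participant
completes 10 trials at each of six set sizes (50–100 by tens) in an
individually randomized order, and types a whole-number estimate

$$\hat x = \max\!\big(1, \mathrm{round}(s \cdot \beta_i \cdot e^{\varepsilon})\big),
\qquad \beta_i = e^{\mathcal N(\mu, \tau^2)},\quad
\varepsilon \sim \mathcal N(0, \sigma_w^2),$$

a multiplicative lognormal response model: numerosity errors scale with the
displayed count, and the error metric is proportional, so a multiplicative
model is the natural generator family. $\beta_i$ is a stable person-level
bias (underestimation when $\mu < 0$, the dominant direction in numerosity
estimation), $\varepsilon$ trial-level noise.

The closed form
$E[(\beta e^{\varepsilon}-1)^2] = e^{2\mu+2s^2} - 2e^{\mu+s^2/2} + 1$ with
$s^2 = \tau^2 + \sigma_w^2$ (exposed as `expected_first_guess_msep()`)
calibrates the default regimes:

* **novice**: $\mu = -0.38$, $\tau = 0.15$, $\sigma_w = 0.30$, giving
  expected first-guess MSE$_P \approx 0.139$ — the level at which untrained
  participants perform in this task family ($a + b \approx 0.14$);
* **trained**: $\mu = -0.13$, $\tau = 0.12$, $\sigma_w = 0$, giving
  $\approx 0.025$, roughly five times more accurate, with *perfectly
  repeatable* responses within a person.

The zero within-person noise of the trained regime is a deliberate
idealization of the expert condition — experts give essentially the same
answer every time they are asked, so the inner crowd has no diversity to
aggregate and its $a$ is genuinely null. It is worth recording why the
idealization is needed: squared-proportional-error curves carry scale-free
relative information, so under this generator family *any* nonzero
$\sigma_w$, however small, eventually yields a decisively nonzero
(if minute) $a$ — shrinking the noise shrinks the estimate but not the
evidence. Real expert data reach the null by a messier route (quantized,
drifting, correlated responses whose within-person variation does not
aggregate away); the generator reaches it by the clean limiting case.
Training is modelled only through its effect (parameter shrinkage); practice
trials are not simulated as events, since only critical trials enter any
analysis.

Seeding fans a master seed into named substreams (one per participant, per
crowd, per pipeline stage) through a deterministic string hash, so
enlarging the sample leaves earlier participants' data bit-identical and
stages can be re-run independently. `inject_typos()` corrupts each record
with a given probability by a slipped order of magnitude (×10 or ÷10),
emulating the keyboard errors the magnitude filter exists to catch.

What the generator does *not* emulate: sequential effects (anchoring on
one's previous response), attention drift, Weber-law scaling of noise with
set size beyond the multiplicative structure, round-number response habits,
or any perceptual model of numerosity. Passing tests therefore certify the
*pipeline* — construction, decomposition, fitting, and evidence direction
under the stated response model — not the psychology of real crowds.

## Problem sizes and tolerances used by the test suite

Monte-Carlo checks in the suite use sizes chosen to keep the full run in
minutes while leaving comfortable statistical margins: parameter-recovery
coverage uses 60 units × 10 aggregate sizes per replicate, 20 replicates,
2 chains × 1500 retained draws (coverage of joint 95% intervals must be
≥ 80%); regime-contrast fits use 30 participants at the full 6 × 10 design
with thinned chains (2 × 1500, thin 2); estimator identities use
$5\times10^4$–$10^5$ draws. The pipeline's default `mcmc_config()` is
4 chains × 2000 draws after 1000 warmup — the setting a real analysis
should start from.

## Known limitations

* Population-level estimates are geometric-mean unit levels (see above);
  comparisons with additive-random-effect fits of the same data will differ
  when unit-level parameters are strongly skewed.
* The Gaussian observation model ignores the heteroscedastic, chi-square
  character of squared-error observations; the gamma option helps with
  positivity but not with the $t$-dependent variance. Both likelihoods
  recover generating parameters well in the tested regimes.
* Savage-Dickey BF$_{10}$ values are capped at $10^6$; beyond that the
  kernel estimate of a vanishing density is pure extrapolation.
* With $n$ crowds of size 10 drawn from $n$ participants, outer crowds
  share members, so their curves are positively correlated; the hierarchy
  treats them as exchangeable units, as the original design does.
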