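---
title: "Methods: interval estimation for the ratio of delta-lognormal variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval estimation for the ratio of delta-lognormal variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlnratio)
```

## The model

A delta-lognormal population $\Delta(\mu, \sigma^2, \delta)$ places
probability $\delta$ on an exact zero and probability $1 - \delta$ on a
lognormal positive value, $\log X \sim N(\mu, \sigma^2)$. The model fits
measurement processes where a detector either records nothing (a dry week at
a rain substation, an empty trawl) or a right-skewed positive amount. Its
variance is

$$\omega = (1 - \delta)\, e^{2\mu + \sigma^2}\left[e^{\sigma^2} - (1 -
\delta)\right],$$

always positive because $e^{\sigma^2} > 1 \ge 1 - \delta$. Two populations
are compared through $\theta = \ln \omega_1 - \ln \omega_2$; all six
interval estimators in this package target $\theta$, and the ratio-scale
view $e^\theta$ is a monotone relabelling of the same interval.

From a sample, the package uses the maximum-likelihood summaries
$\hat\delta = n_0/n$, $\hat\mu$ the mean of the log-positives, and
$\hat\sigma^2$ the variance of the log-positives **with divisor $n_1$** (the
number of positives), not $n_1 - 1$. Every formula downstream assumes this
convention; feeding an unbiased variance estimate instead shifts each
method by $O(1/n_1)$. Zeros are detected by exact equality with 0 — the
recording convention for rainfall-type data — with no tolerance. Groups
with no zeros at all are accepted ($\hat\delta = 0$, with a warning),
since every formula stays finite there.

## The six estimators

**GCI.** For each of $m$ Monte-Carlo draws, the zero proportion is pivoted
through the arcsine variance-stabilizing transform,
$R_\delta = \sin^2[\arcsin\sqrt{\hat\delta} - W/(2\sqrt n)]$ with
$W \sim N(0,1)$; the log-scale variance through
$R_{\sigma^2} = (n_1 - 1)\hat\sigma^2 / U$ with
$U \sim \chi^2_{n_1 - 1}$; and the mean through
$R_\mu = \hat\mu - Z\sqrt{R_{\sigma^2}/n_1}$. These assemble into a draw of
$\ln\omega$ per group and a draw of $\theta$; the equal-tailed empirical
percentile interval of the $m$ draws is the GCI.

**FGCI.** Identical in the $(\mu, \sigma^2)$ pivots — with the chi-square
variate entering pre-scaled by its degrees of freedom, the only scaling
under which the variance pivot is a valid fiducial quantity, where it
coincides algebraically with the GCI pivot — but the *positive-class*
probability is drawn from its beta fiducial distribution
$\mathrm{beta}(n_1 + \tfrac12, n_0 + \tfrac12)$. Because the two
constructions share the dominant $\sigma^2$ pivot exactly and differ only
in how a proportion is perturbed, GCI and FGCI intervals are nearly
indistinguishable at realistic sample sizes; the test suite checks both the
shared algebra and the numerical agreement.

**MOVER.** $\ln\omega$ decomposes exactly as
$\ln(1-\delta) + (2\mu + \sigma^2) + \ln[e^{\sigma^2} - (1-\delta)]$.
Each component receives its own closed-form interval — a log-scale Wilson
score interval for the proportion term; normal-plus-chi-square margins for
the linear term; combined margins for the bracket term — and the component
margins are recovered by root-sum-of-squares into an interval for
$\ln\omega$, then once more for the difference $\theta$. The construction
uses fixed normal and chi-square quantiles throughout, so it is fully
deterministic: identical inputs give bit-identical intervals, and swapping
the groups maps $(L, U)$ to exactly $(-U, -L)$.

**HPD intervals.** All three priors admit direct conjugate sampling — no
MCMC. Under Jeffreys, $\sigma^{2*} \sim IG(r/2,\, r\hat\sigma^2/2)$ with
$r = n_1 - 1$, $\mu^* \mid \sigma^{2*} \sim N(\hat\mu, \sigma^{2*}/n_1)$,
and the zero probability $\delta^* \sim \mathrm{beta}(n_0 + \tfrac12,
n_1 + \tfrac12)$; Jeffreys' Rule differs only in the constants
($r \mapsto n_1 + 1$, beta second shape $\tfrac12 \mapsto \tfrac32$). The
normal-gamma prior treats $(\mu, 1/\sigma^2)$ as conjugate normal-gamma,
giving $\sigma^{2*} \sim IG\big(\tfrac{n_1-1}{2},\,
\tfrac{n_1\hat\sigma^2}{2}\big)$ and a Student-$t$ marginal for $\mu^*$
with $n_1 - 1$ degrees of freedom, location $\hat\mu$ and squared scale
$\hat\sigma^2/(n_1 - 1)$, while the **positive-class** probability gets a
symmetric $\mathrm{beta}(d, d)$ prior with $d = (2 + z^2_{\zeta/2})/6$,
yielding $\mathrm{beta}(n_1 + d, n_0 + d)$ a posteriori. Draws transform
through the variance formula to $\ln\omega^*$ and $\theta^*$, and the HPD
interval of the $m$ differences is reported.

## Tunable parameters

* `level` (default 0.95): nominal confidence/credibility $1 - \zeta$. The
  normal-gamma beta constant $d$ is tied to it ($d \approx 0.9736$ at 95%)
  and is recomputed whenever the level changes.
* `m` (default 2500): Monte-Carlo draws per sampling-based interval. The
  endpoints of a single run at $m = 2500$ carry roughly 3–4% Monte-Carlo
  noise on the ratio scale for rainfall-sized samples; averaging over seeds
  or raising `m` tightens them as $1/\sqrt m$.
* `M` (default 5000): simulation replicates per scenario cell; the binomial
  standard error of a coverage estimate at $M = 5000$ is about 0.3
  percentage points near 95%.
* `seed`: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; nothing depends on hidden global state. Inside
  `run_scenario()` per-replicate substreams are derived from the scenario
  seed, so every method sees identical replicate datasets (a paired design
  that removes dataset noise from length comparisons).

## Numerical conventions

* **Empirical quantiles** use linear interpolation between order statistics
  (`stats::quantile()` type 7), applied uniformly to GCI and FGCI draws.
  The convention matters only at $O(1/m)$ but is fixed so results are
  bit-reproducible given a seed.
* **HPD extraction** is the shortest-window estimator on the sorted sample:
  among all contiguous windows of $\lceil \mathrm{level} \cdot m \rceil$
  order statistics the narrowest is returned, earliest window on ties. The
  test suite checks it against a brute-force enumeration oracle.
* **Inverse-gamma** is parameterized as shape/rate, density
  $\propto x^{-a-1} e^{-b/x}$, so $IG(a, b)$ has mean $b/(a-1)$; the
  closed-form mean is asserted in the tests. Student-$t$ draws are
  location–scale transforms of a standard $t$.
* **MOVER bracket component.** The margins for the third component combine
  an exponentiated chi-square term for $\hat\sigma^2$ with the squared
  Wilson half-width, and are applied to the *untransformed* quantity
  $A = e^{\hat\sigma^2} - (1 - \hat\delta)$ before taking the log
  ($L = \ln(A - s_l)$, $U = \ln(A + s_u)$). Applying them after the log
  instead is undefined on realistic data ($s_l \ge 1$ always, while the
  logged component is often below 1); of the candidate readings we
  examined, only this one reproduces the published two-region rainfall
  interval that the construction was validated against, and it is the one
  implemented.
* **Degenerate cases.** When $A \le s_l$ — small $\hat\sigma^2$, roughly
  $\hat\sigma^2 < \ln(2 - \hat\delta)$ — the bracket component's lower
  bound does not exist; it is set to $-\infty$ with a warning and
  propagates to the MOVER lower bound. In simulations at $n = 15$,
  $\sigma^2 = 1$ this affects a non-negligible share of replicates, so
  `run_scenario()` averages lengths over the replicates where all requested
  intervals are finite (reporting the dropped count as `n_infinite`);
  coverage still uses all replicates, since a half-infinite interval either
  contains $\theta$ or not. Replicate datasets with fewer than two positive
  values in a group are redrawn and counted (`n_degenerate`); with
  $\delta \le 0.5$ and $n \ge 15$ this is rare.

## The synthetic-data generator

`rdln()` draws zeros as independent Bernoulli($\delta$) indicators and
positives as $\exp(N(\mu, \sigma^2))$ — exactly the model the estimators
assume, which is the point: the simulation harness measures each method's
calibration *under the model*. The default study conditions
($\mu = 3$, $\sigma^2 = 1$, $\delta$ between 0.1 and 0.5, group sizes 15
to 100, $M = 5000$, $m = 2500$, level 0.95) mirror rainy-season rainfall
records at substation networks of realistic size. What the generator does
*not* emulate: spatial correlation between nearby substations,
heavier-than-lognormal positive tails, measurement rounding near zero, and
misclassified trace values. A method that covers well here can therefore
still miscover on real data whose positives are not lognormal; the
simulation results say nothing about that robustness.

## Test and acceptance problem sizes

The unit suite runs its distributional checks at $m = 10^5$ draws (moment
and two-sample agreement checks) and its coverage properties at
$M \le 2000$ replicates; the acceptance script runs the two headline
simulation cells at the full $M = 5000$, $m = 2500$ and averages the HPD-NG
worked-example endpoints over 20 seeds. These sizes put Monte-Carlo noise
well below every asserted tolerance.

## Design choices made where the design was open

* The FGCI chi-square variate is used in its scaled form
  ($\chi^2_{n_1-1}/(n_1-1)$); the unscaled alternative destroys the
  fiducial validity of the variance pivot and produces intervals orders of
  magnitude off the GCI ones.
* Simulation lengths and RAL are computed on the $\theta$ scale, where all
  six intervals are constructed; ratio-scale lengths are a presentation
  choice for single analyses, not a comparison metric, because $\exp$
  distorts lengths asymmetrically across methods.
* The normal-gamma positive-class draw is stored explicitly as
  `prob_positive` (never as a zero probability) so the reversed beta shape
  roles relative to the Jeffreys parameterization cannot cause sign bugs.
* The true $\theta$ of an equal-parameter scenario is set to exactly 0
  rather than computed by subtraction.

## Known limitations

* The normal-gamma posterior as specified here is slightly *more* dispersed
  than the Jeffreys one in every component (larger inverse-gamma rate,
  wider $t$ scale), so its HPD intervals are a little wider and more
  conservative than the Jeffreys'-Rule baseline, not shorter; reports of a
  shorter normal-gamma interval are not reproducible from these posterior
  densities.
* The MOVER interval under-covers at small $n$ with $\sigma^2 \approx 1$
  (its empirical coverage in the acceptance runs sits several points below
  the nominal 95% at $n_1 = n_2 = 15$), and its lower bound degenerates on
  a visible fraction of such replicates. It remains attractive as the only
  deterministic, instantaneous method, and behaves well on moderate-sized
  real samples such as the rainfall example.
* GCI and FGCI are practically interchangeable for this functional;
  maintaining both is useful mainly for cross-checking.
* All methods condition on at least two positive observations per group;
  heavily zero-inflated tiny samples are outside scope.
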