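---
title: "Correlations under double censoring: theory, estimation, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlations under double censoring: theory, estimation, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cencorr)
```

## The model

Everything in this package rests on one latent model: the uncensored
pair $(X, Y)$ is bivariate normal with means $\mu_x, \mu_y$, standard
deviations $\sigma_x, \sigma_y$ and correlation $\rho$.  What the
researcher records is the *censored* pair

$$x = \min(\max(X, a_x), b_x), \qquad y = \min(\max(Y, a_y), b_y),$$

where $a$ and $b$ are lower and upper limits of detection (either side
may be absent).  A value at a limit carries only the information that
the latent value lies at or beyond it.  This is censoring, not
truncation: the record exists, the exact value does not.

Three consequences of this model organize the package.

### 1. Attenuation of the naive correlation

The Pearson correlation of the censored values has population value

$$\rho_{xy} = \frac{E[xy] - E[x]E[y]}
  {\sqrt{(E[x^2]-E[x]^2)(E[y^2]-E[y]^2)}},$$

with all moments taken under the clamped distribution.  The univariate
moments have closed forms in normal partial moments.  For the cross
moment, `censored_moments()` reduces the double integral to a single
adaptive quadrature over $x$: conditionally on $X = t$, $Y$ is normal
with mean $\rho t$ and standard deviation $\sqrt{1-\rho^2}$ (on the
standardized scale), so the conditional expectation of clamped $Y$ is
again a closed form, and the outer integral is one-dimensional with
integrable kinks at $a_x$ and $b_x$, where the integration is split.
This is exact up to quadrature tolerance for *any* combination of
left/right fractions or fixed thresholds — the 50%/50% special case,
where the clamped variables are half-normal and

$$E[xy] = \frac{\sqrt{1-\rho^2} + \rho(\pi/2 + \arcsin\rho)}{2\pi},$$

is used as a closed-form fast path and as a cross-check of the
quadrature (the two agree to $10^{-6}$ in the test suite, and both
agree with large-sample simulation).

Attenuation is computed for the standard latent model: correlations
are invariant to location and scale, fraction-based limits are
quantiles, and threshold-based limits are standardized internally.
Fixing $\rho = \pm 1$ breaks the two-dimensional density, so
$|\rho| > 1 - 10^{-9}$ is routed through the one-dimensional
pushforward $Y = \pm X$.

A note on one published curve-read value: for $\rho = .707$ under
50/50 left censoring the exact computation gives $\rho_{xy} = .641$.
A figure-derived value of .651 circulates; it is not consistent with
the same source's own derivation for $\rho = -.707$ (which gives
$-.396$, as does this package), so the exact value is the one tested
here.

### 2. The sampling view

`censorcorr()` is the simulation counterpart: draw $n$ latent pairs
(by the conditional construction $y = \rho x + \sqrt{1-\rho^2}\,e$,
which stays exact at $\rho = \pm 1$), censor, correlate.  Censoring a
*sample* raises a choice the analytic theory does not face: is the
limit the population quantile or the sample percentile?  The
simulator's default is the sample rule — the threshold is the order
statistic at rank $\lceil pn \rceil$ and exactly that many values
(ties broken by rank) are moved to it — because that is how censoring
is imposed in simulation studies of this design, it guarantees the
stated share is censored, and the replacement value is an attained
data value.  Population mode exists and is what the agreement tests
against the quadrature use, since the analytic $\rho_{xy}$ is defined
with population quantiles.  The default $n$ of 500{,}000 makes the
Monte-Carlo standard error $(1-r^2)/\sqrt{n}$ of order $10^{-3}$.

### 3. The likelihood view

`fit_censored()` recovers $\rho$ (and the nuisance means and SDs) by
full-information maximum likelihood.  Each pair contributes by its
censoring pattern:

* both observed — the bivariate normal log density;
* $x$ censored at $a$, $y$ observed — $\log\{\varphi(y)\,
  \Phi(\pm(a - \mu_{x|y})/\sigma_{x|y})\}$ with the usual conditional
  mean and SD, the sign choosing the lower or upper tail;
* both censored — the log rectangle probability of the censored
  quadrant.

Rectangle probabilities use `pbvnorm()`, an adaptive one-dimensional
quadrature of $\varphi(t)\,\Phi((k-\rho t)/\sqrt{1-\rho^2})$
(tolerance $10^{-10}$); no installed dependency provides a bivariate
normal CDF, and since all censored values of a sample share their
limits, each likelihood evaluation needs at most four rectangle
values, so adaptive quadrature costs essentially nothing.  Tail
probabilities are accumulated on the log scale to avoid underflow.
The score vector is computed analytically (inverse-Mills terms for
single-censored contributions, the derivative identities of the
bivariate CDF for rectangles) and is verified against central
differences to $10^{-8}$ in the tests; `nlminb` uses it, as does the
observed-information Hessian behind the Wald intervals.

Two parameterizations mirror the two ways practitioners set this
model up:

* **unconstrained** — $\rho$ enters the search directly.  This is the
  analogue of estimating an unrestricted covariance: nothing keeps the
  estimate away from the boundary.  Because the likelihood itself is
  undefined beyond $\pm 1$ on the correlation scale, estimates outside
  the valid range surface here as boundary-pinned optima rather than
  as numbers beyond $\pm 1$.
* **constrained** (default) — $\rho = \tanh(\eta)$, so any optimum is
  a valid correlation strictly inside $(-1, 1)$.  This reproduces the
  effect of a positive-definiteness constraint without reproducing any
  particular implementation of one.

Starting values are moments of the censored data with the Pearson r
clamped to $\pm.95$.  Convergence is declared when `nlminb` reports
success *or* the analytic score is numerically zero
($\max|g| < 10^{-2}$) at the returned optimum with a finite
objective; the second clause matters because tight step tolerances
(relative tolerance $10^{-12}$, step tolerance $10^{-11}$, 500
iterations) can make the optimizer label a genuine optimum "singular
convergence".  Identification requires at least 5 cases and one
observed value per variable — fully observed *pairs* are not
required, because under severe censoring of a strongly correlated
pair complete pairs are vanishingly rare while the correlation
remains identified through the single-censored tails.

**Intervals.**  Wald intervals are built on the working scale
($\rho$ directly, or $\eta$ and mapped through $\tanh$ — hence the
constrained interval can never reach width 2, and the
width-$\ge$-2 pathology an unrestricted covariance parameterization
can show is structurally absent here).  Profile intervals invert the
likelihood-ratio test: endpoints sit where the profile log-likelihood,
with nuisance parameters re-maximized at each fixed $\rho$, drops
$\chi^2_1(.95)/2 \approx 1.92$ below the maximum, found by geometric
bracketing and bisection on each side.  "The 2.5th and 97.5th
percentiles of the log-likelihood" is sometimes used loosely for this
construction; the likelihood-ratio inversion is the standard meaning
and is what is implemented.  Endpoints cannot leave $(-1, 1)$; a side
that reaches the boundary without crossing the cutoff is clamped there
and the interval flagged not-converged.

## The evaluation harness

`run_cell()` and `run_study()` reproduce the design of a
Monte-Carlo evaluation of this estimator: cells of
$\rho \times \text{censoring pattern} \times n$, by default 1000
trials per replication and two replications per cell, with the five
left-censoring patterns 30/30, 50/50, 70/70, 0/50 and 30/70 (percent
on $x$/$y$), $\rho \in \{\pm.3, \pm.7, \pm.9, \pm 1\}$ and
$n \in \{200, 500\}$.  Per-trial seeds are mixed deterministically
from (master seed, cell index, replication, trial), so any cell can be
re-run in isolation and results do not depend on execution order.
Summaries per cell: six point-estimate statistics (convergence
proportion, mean, SD, min, max, bias, RMSE — bias and RMSE over
converged trials) and seven interval statistics (convergence
proportion, mean midpoint, coverage, max/mean/median width, proportion
of widths $\ge 2$).  A zero-width interval $[c, c]$ covers iff
$c$ equals $\rho$ exactly — the natural reading of the coverage
definition, stated here because it matters only in the degenerate
$\rho = \pm 1$ cells.  `pool_replications()` averages replications;
uncensored baselines come from the classical formulas
(`reference_uncensored_rmse()`: $\sqrt{SE^2 + \text{bias}^2}$ with
$SE = \sqrt{(1-\rho^2)/(n-2)}$ and bias $\approx -\rho(1-\rho^2)/2n$;
`reference_uncensored_ci_width()`: the Fisher $r$-to-$z$ interval
width).  Printed 3-decimal tables of the Fisher widths in the
literature are truncated rather than rounded (e.g. the exact .1429 at
$\rho=.7$, $n=200$ appears as .142); tests compare within one unit of
the last printed digit.

### What the generator does and does not emulate

The synthetic data are exactly the study conditions the estimator is
designed for: bivariate normal latent pairs, sharp known limits,
censoring by the sample-percentile rule.  Passing tests therefore
demonstrate correctness of the machinery and calibration *under
normality with known censoring status*.  They do not speak to skewed
or discrete latent distributions, misrecorded censoring statuses,
interval censoring, or more than two variables — all outside this
package's scope.

### Problem sizes in the shipped tests

The full 80-cell × 2000-trial design is more than the package's test
suite needs to verify behavior, so the suite runs the informative
slices at reduced but statistically meaningful scale: 300 trials per
benchmark cell (500 where a coverage proportion is the quantity of
interest), 300 replicates per parameter-recovery cell across all five
patterns at $\rho = \pm.3, \pm.7$, $n = 500$, and Monte-Carlo
agreement checks at $n = 5\times 10^4$.  All Monte-Carlo assertions
carry explicit error allowances (two standard errors of the simulated
statistic on top of the anchor's printed rounding), fixed in advance
of the runs.  Known benchmark behaviors these runs reproduce: RMSE
$\approx .05$ at $(\rho=.3, n=500, 50/50)$; mean estimate near
$-.955$ (bias $\approx -.06$ at $n = 200$) at $(\rho=-.9, 70/70)$ —
the one genuinely biased region, severe censoring of a strong
negative correlation; and constrained-Wald coverage of at least 94%
at $(\rho=.7, n=500, 50/50)$.

## Known limitations

* Latent normality is assumed everywhere; no robustness machinery.
* Interval censoring (grouped/rounded data) is not modeled.
* Bivariate only: multivariate extensions (factor models, SEM) are
  out of scope, though the attenuation tools apply pairwise.
* Profile intervals under severe censoring of strong negative
  correlations can fail to bracket a crossing before the boundary;
  they are then clamped and flagged, matching the known fragility of
  profile intervals in that region.
* The unconstrained parameterization reports boundary-pinned optima
  where an unrestricted covariance search would report invalid
  estimates; the convergence flag, not the estimate's value, carries
  that information.
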