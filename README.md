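# cencorr

Correlation estimation for doubly censored bivariate normal data.

## The problem

Censoring — floor and ceiling effects, limits of detection, study
end-points — records a value only as "at or below a" (left censoring)
or "at or beyond b" (right censoring).  When *both* members of a
correlated pair (x, y) are censored, the Pearson correlation of the
recorded values is a distorted estimate of the latent correlation
ρ_XY, and the distortion is asymmetric: with both variables
left-censored (or both right-censored) negative correlations are hit
hardest, while with one floor and one ceiling positive correlations
are.  Under 50% left censoring of a standard bivariate normal pair,

    ρ_xy = ( E[xy] − 1/2π ) / ( 1/2 − 1/2π ),
    E[xy] = ( √(1 − ρ²) + ρ (π/2 + asin ρ) ) / 2π,

so a perfect ρ_XY = −1 is observed as ρ_xy = −1/(π − 1) ≈ −.467,
while ρ_XY = +1 survives unchanged.  This asymmetry can, for example,
push negatively keyed questionnaire items onto spurious separate
factors.

`cencorr` provides, for users of censored psychological, biomedical or
environmental measurements:

* **Attenuation theory** — `attenuated_correlation()` computes ρ_xy
  for any mix of left/right censoring fractions or fixed thresholds,
  by half-normal closed forms where available and adaptive quadrature
  of the clamped-moment integrals otherwise.
* **A censoring simulator** — `censorcorr()` draws large seeded
  bivariate normal samples, censors them by the sample-percentile
  rule, and reports the naive Pearson r with its Monte-Carlo error.
* **A tobit-type ML estimator** — `fit_censored()` maximizes the
  full-information censored-Gaussian likelihood (densities for
  observed pairs, conditional tails for half-censored pairs,
  rectangle probabilities for doubly censored pairs) to recover
  ρ_XY from censored data; `wald_ci()` and `profile_ci()` give
  confidence intervals, with a bounded (atanh-parameterized) variant
  that cannot produce invalid correlations.
* **A simulation-study harness** — `run_study()` evaluates bias,
  RMSE, convergence, coverage and interval width over grids of
  ρ × censoring pattern × sample size, with per-cell reproducible
  seeding, plus the classical uncensored references
  (`reference_uncensored_rmse()`, `reference_uncensored_ci_width()`).

## Worked example

Simulate a strongly negative latent correlation (ρ_XY = −.707, the
cosine of 135°), censor half of each variable at its floor, and
compare the naive and corrected analyses:

```r
library(cencorr)

d  <- sample_latent(bvn_model(rho = -0.707), 400, seed = 2024)
cs <- censor_sample(d$x, d$y, censoring_scheme(left_x = 0.5, left_y = 0.5))
cs
#> Censored sample: n = 400
#>   x: 200 obs, 200 left, 0 right
#>   y: 200 obs, 200 left, 0 right

censored_pearson(cs)          # naive analysis
#> [1] -0.389

attenuated_correlation(-0.707, censoring_scheme(left_x = .5, left_y = .5))
#> Attenuated correlation (closed_form)
#>   latent rho = -0.707  ->  censored rho = -0.396

fit <- fit_censored(cs)       # tobit-type ML correction
fit
#> Censored bivariate normal ML fit (constrained)
#>   rho_hat = -0.7280  loglik = -757.819  converged = TRUE
wald_ci(fit, cs)
#> 95% confidence interval (wald_constrained)
#>   [-0.7865, -0.6566]  width 0.1298
```

The naive correlation (−.389) sits at the theoretical attenuated value
(−.396), far from the truth; the ML estimate (−.728, CI covering
−.707) recovers it.

A shell interface mirrors the library
(`inst/exec/cencorr attenuate|simulate|fit|study`), e.g.
`cencorr attenuate --rho -1 --left-x 0.5 --left-y 0.5` prints `-0.467`.

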