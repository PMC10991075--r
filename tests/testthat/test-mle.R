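test_that("likelihood contributions match brute-force quadrature", {
  set.seed(51)
  model <- bvn_model(mu_x = 0.3, mu_y = -0.2, sigma_x = 1.2,
                     sigma_y = 0.8, rho = -0.55)
  for (rep in 1:5) {
    d <- sample_latent(bvn_model(rho = runif(1, -0.8, 0.8)), 12,
                       seed = 500 + rep)
    scheme <- censoring_scheme(left_x = 0.25, right_x = 0.15,
                               left_y = 0.3)
    cs <- censor_sample(d$x, d$y, scheme)
    expect_equal(loglik_censored(model, cs), oracle_loglik(model, cs),
                 tolerance = 1e-6)
  }
  # right-censoring and mixed-side rectangles
  d <- sample_latent(bvn_model(rho = 0.5), 12, seed = 520)
  cs <- censor_sample(d$x, d$y,
                      censoring_scheme(right_x = 0.4, right_y = 0.3))
  expect_equal(loglik_censored(model, cs), oracle_loglik(model, cs),
               tolerance = 1e-6)
  cs <- censor_sample(d$x, d$y,
                      censoring_scheme(left_x = 0.5, right_y = 0.4))
  expect_equal(loglik_censored(model, cs), oracle_loglik(model, cs),
               tolerance = 1e-6)
})

test_that("uncensored likelihood and independent halves are exact", {
  d <- sample_latent(bvn_model(rho = 0.3), 50, seed = 61)
  cs <- censored_sample(d$x, d$y)
  m <- bvn_model(0.1, -0.1, 1.1, 0.9, 0.25)
  expect_equal(loglik_censored(m, cs),
               sum(dbvnorm(d$x, d$y, m, log = TRUE)), tolerance = 1e-10)

  # rho = 0, both members censored at the means: log(1/4)
  cs2 <- censored_sample(0, 0, "left", "left", c(0, Inf), c(0, Inf))
  expect_equal(loglik_censored(bvn_model(rho = 0), cs2), log(0.25),
               tolerance = 1e-9)

  # perfect correlation with a censored case degenerates to -Inf
  expect_identical(loglik_censored(bvn_model(rho = 1), cs2), -Inf)
})

test_that("analytic gradient matches central differences", {
  d <- sample_latent(bvn_model(rho = -0.6), 60, seed = 71)
  cs <- censor_sample(d$x, d$y,
                      censoring_scheme(left_x = 0.4, right_y = 0.3))
  numgrad <- function(f, x, h = 1e-6) {
    vapply(seq_along(x), function(i) {
      e <- replace(rep(0, length(x)), i, h)
      (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1))
  }
  for (par in c("constrained", "unconstrained")) {
    th <- c(0.2, -0.3, log(1.2), log(0.8),
            if (par == "constrained") atanh(-0.5) else -0.5)
    expect_equal(
      cencorr:::grad_neg_loglik_theta(th, cs, par),
      numgrad(function(t) cencorr:::neg_loglik_theta(t, cs, par), th),
      tolerance = 1e-5)
  }
})

test_that("uncensored ML estimate equals the closed-form Gaussian MLE", {
  d <- sample_latent(bvn_model(rho = 0.6), 120, seed = 81)
  cs <- censored_sample(d$x, d$y)
  r <- cor(d$x, d$y)
  for (par in c("constrained", "unconstrained")) {
    f <- fit_censored(cs, par)
    expect_true(f$converged)
    expect_equal(f$model_hat$rho, r, tolerance = 1e-6)
    expect_equal(f$model_hat$mu_x, mean(d$x), tolerance = 1e-6)
    # ML variance uses 1/n
    expect_equal(f$model_hat$sigma_x,
                 sqrt(mean((d$x - mean(d$x))^2)), tolerance = 1e-5)
  }
})

test_that("fits are equivariant under location-scale and mirroring", {
  d <- sample_latent(bvn_model(rho = 0.55), 200, seed = 91)
  scheme <- censoring_scheme(left_x = 0.5, left_y = 0.5)
  cs <- censor_sample(d$x, d$y, scheme)
  f0 <- fit_censored(cs)

  # location-scale: transform data and limits alike
  a <- 3.5; b <- 0.4
  cs_ls <- censored_sample(a + b * cs$x, cs$y, cs$x_status, cs$y_status,
                           a + b * cs$x_limits, cs$y_limits)
  f_ls <- fit_censored(cs_ls)
  expect_equal(f_ls$model_hat$rho, f0$model_hat$rho, tolerance = 1e-6)
  expect_equal(f_ls$model_hat$mu_x, a + b * f0$model_hat$mu_x,
               tolerance = 1e-5)

  # mirroring y negates the estimate
  cs_m <- censored_sample(cs$x, -cs$y, cs$x_status,
                          ifelse(cs$y_status == "left", "right",
                                 ifelse(cs$y_status == "right", "left",
                                        "obs")),
                          cs$x_limits, sort(-cs$y_limits))
  f_m <- fit_censored(cs_m)
  expect_equal(f_m$model_hat$rho, -f0$model_hat$rho, tolerance = 1e-6)
})

test_that("constrained and unconstrained optima coincide when interior", {
  for (seed in c(101, 102)) {
    d <- sample_latent(bvn_model(rho = 0.5), 300, seed = seed)
    cs <- censor_sample(d$x, d$y,
                        censoring_scheme(left_x = 0.3, left_y = 0.3))
    fc <- fit_censored(cs, "constrained")
    fu <- fit_censored(cs, "unconstrained")
    expect_true(fc$converged && fu$converged)
    expect_equal(fc$model_hat$rho, fu$model_hat$rho, tolerance = 1e-4)
  }
})

test_that("identification failures raise errors", {
  cs <- censored_sample(rep(0, 6), rnorm(6), rep("left", 6), rep("obs", 6),
                        c(0, Inf), c(-Inf, Inf))
  expect_error(fit_censored(cs), "unidentified")
  tiny <- censored_sample(rnorm(3), rnorm(3))
  expect_error(fit_censored(tiny), "at least 5")
})

test_that("Wald intervals have the defining width and nest with level", {
  d <- sample_latent(bvn_model(rho = 0.7), 300, seed = 111)
  cs <- censor_sample(d$x, d$y, censoring_scheme(left_x = 0.5, left_y = 0.5))
  f <- fit_censored(cs)
  ci95 <- wald_ci(f, cs)
  ci90 <- wald_ci(f, cs, level = 0.90)
  expect_true(ci95$converged)
  # constrained intervals always lie inside (-1, 1)
  expect_gt(ci95$lower, -1)
  expect_lt(ci95$upper, 1)
  expect_true(ci90$lower > ci95$lower && ci90$upper < ci95$upper)

  # unconstrained width is exactly 2 z SE on the rho scale
  fu <- fit_censored(cs, "unconstrained")
  ciu <- wald_ci(fu, cs)
  expect_equal(ciu$width, 2 * qnorm(0.975) * ciu$se_rho, tolerance = 1e-10)
  expect_equal(ciu$midpoint, fu$model_hat$rho, tolerance = 1e-8)
})

test_that("Wald width on uncensored data tracks the Fisher reference", {
  widths <- vapply(1:20, function(i) {
    d <- sample_latent(bvn_model(rho = 0.7), 200, seed = 2000 + i)
    cs <- censored_sample(d$x, d$y)
    f <- fit_censored(cs)
    wald_ci(f, cs)$width
  }, numeric(1))
  ref <- reference_uncensored_ci_width(0.7, 200)
  expect_lt(abs(mean(widths) - ref) / ref, 0.15)
})

test_that("profile intervals invert the likelihood ratio", {
  d <- sample_latent(bvn_model(rho = 0.6), 250, seed = 121)
  cs <- censor_sample(d$x, d$y, censoring_scheme(left_x = 0.3, left_y = 0.3))
  f <- fit_censored(cs)
  pc <- profile_ci(f, cs)
  expect_true(pc$converged)
  expect_gt(pc$lower, -1)
  expect_lt(pc$upper, 1)
  expect_true(pc$lower < f$model_hat$rho && f$model_hat$rho < pc$upper)

  # near-quadratic likelihood: profile ~ Wald (likelihood-ratio/Wald
  # asymptotic equivalence)
  wc <- wald_ci(f, cs)
  expect_lt(abs(pc$lower - wc$lower), 0.02)
  expect_lt(abs(pc$upper - wc$upper), 0.02)

  # nesting with level
  pc90 <- profile_ci(f, cs, level = 0.90)
  expect_true(pc90$lower > pc$lower && pc90$upper < pc$upper)

  # endpoints sit where the profile log-likelihood drops by chi2/2
  drop <- qchisq(0.95, 1) / 2
  prof_at <- function(rho) {
    obj <- function(nu) {
      cencorr:::neg_loglik_theta(c(nu, atanh(rho)), cs, "constrained")
    }
    -nlminb(f$theta[1:4], obj)$objective
  }
  expect_equal(prof_at(pc$lower), f$loglik - drop, tolerance = 1e-3)
  expect_equal(prof_at(pc$upper), f$loglik - drop, tolerance = 1e-3)
})
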