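# Shared fixtures and independent oracles.

scheme_5050_left <- censoring_scheme(left_x = 0.5, left_y = 0.5)
scheme_5050_lr <- censoring_scheme(left_x = 0.5, right_y = 0.5)

# The five left-censoring patterns of the package's study design
study_patterns <- list(
  "30/30" = censoring_scheme(left_x = 0.3, left_y = 0.3),
  "50/50" = censoring_scheme(left_x = 0.5, left_y = 0.5),
  "70/70" = censoring_scheme(left_x = 0.7, left_y = 0.7),
  "0/50"  = censoring_scheme(left_y = 0.5),
  "30/70" = censoring_scheme(left_x = 0.3, left_y = 0.7)
)

# Brute-force quadrature oracle for a single likelihood contribution:
# integrates the bivariate normal density over the censored region,
# independently of the conditional-decomposition formulas in the
# package.
oracle_contribution <- function(model, x, y, x_status, y_status) {
  lim <- function(st, v) {
    switch(st, obs = NULL, left = c(-Inf, v), right = c(v, Inf))
  }
  lx <- lim(x_status, x); ly <- lim(y_status, y)
  if (is.null(lx) && is.null(ly)) {
    return(log(dbvnorm(x, y, model)))
  }
  if (is.null(ly)) {
    v <- integrate(function(t) dbvnorm(t, rep(y, length(t)), model),
                   lx[1], lx[2], rel.tol = 1e-10)$value
    return(log(v))
  }
  if (is.null(lx)) {
    v <- integrate(function(t) dbvnorm(rep(x, length(t)), t, model),
                   ly[1], ly[2], rel.tol = 1e-10)$value
    return(log(v))
  }
  inner <- function(t) {
    vapply(t, function(ti) {
      integrate(function(u) dbvnorm(rep(ti, length(u)), u, model),
                ly[1], ly[2], rel.tol = 1e-9)$value
    }, numeric(1))
  }
  log(integrate(inner, lx[1], lx[2], rel.tol = 1e-8)$value)
}

oracle_loglik <- function(model, cs) {
  sum(vapply(seq_len(cs$n), function(i) {
    oracle_contribution(model, cs$x[i], cs$y[i],
                        cs$x_status[i], cs$y_status[i])
  }, numeric(1)))
}

# Quick simulated fit of one trial of a study cell
one_trial_fit <- function(rho, scheme, n, seed,
                          parameterization = "constrained") {
  d <- sample_latent(bvn_model(rho = rho), n, seed = seed)
  cs <- censor_sample(d$x, d$y, scheme)
  fit_censored(cs, parameterization)
}
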