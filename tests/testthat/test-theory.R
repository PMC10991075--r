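test_that("angles translate to correlations via the cosine rule", {
  expect_equal(rho_from_angle(180), -1)
  expect_equal(rho_from_angle(90), 0)
  expect_equal(rho_from_angle(135), -sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(round(rho_from_angle(135), 3), -0.707)
  expect_equal(rho_from_angle(0), 1)
  expect_error(rho_from_angle(Inf), "finite")
  expect_error(rho_from_angle(NA_real_), "finite")
})

test_that("half-normal moments hold under 50/50 left censoring", {
  for (rho in c(-0.7, 0, 0.5)) {
    m <- censored_moments(bvn_model(rho = rho), scheme_5050_left)
    expect_equal(m$e_x, sqrt(1 / (2 * pi)), tolerance = 1e-10)
    expect_equal(m$e_y, sqrt(1 / (2 * pi)), tolerance = 1e-10)
    expect_equal(m$e_x2, 0.5, tolerance = 1e-10)
    expect_equal(m$e_y2, 0.5, tolerance = 1e-10)
    # variances nonnegative
    expect_gte(m$e_x2, m$e_x^2)
    expect_gte(m$e_y2, m$e_y^2)
  }
})

test_that("cross moment matches closed form, quadrature and Monte Carlo", {
  # closed form verified against large-n simulation and independent
  # quadrature; perfectly opposite half-normals never co-occur
  m <- censored_moments(bvn_model(rho = -1), scheme_5050_left)
  expect_equal(m$e_xy, 0, tolerance = 1e-9)

  for (rho in c(-0.707, -0.2, 0.5, 0.9)) {
    closed <- cencorr:::halfnormal_cross_moment(rho)
    quad <- censored_moments(bvn_model(rho = rho), scheme_5050_left)$e_xy
    expect_equal(quad, closed, tolerance = 1e-6)
  }
  expect_equal(cencorr:::halfnormal_cross_moment(0.5), 0.3044989,
               tolerance = 1e-6)

  set.seed(101)
  n <- 1e6
  x <- rnorm(n); e <- rnorm(n)
  rho <- 0.5
  y <- rho * x + sqrt(1 - rho^2) * e
  mc <- mean(pmax(x, 0) * pmax(y, 0))
  se <- sd(pmax(x, 0) * pmax(y, 0)) / sqrt(n)
  expect_lt(abs(mc - cencorr:::halfnormal_cross_moment(rho)), 4 * se)
})

test_that("attenuation reproduces the 50% censoring special cases", {
  r1 <- attenuated_correlation(-1, scheme_5050_left)
  expect_equal(round(r1$rho_censored, 3), -0.467)
  expect_equal(r1$rho_censored, -1 / (pi - 1), tolerance = 1e-9)
  expect_identical(r1$method, "closed_form")

  expect_equal(round(attenuated_correlation(-0.707,
                                            scheme_5050_left)$rho_censored, 3),
               -0.396)
  expect_equal(round(attenuated_correlation(1,
                                            scheme_5050_lr)$rho_censored, 3),
               0.467)
  # the exact value for rho = .707 under 50/50 left (the curve-read
  # in-text figure value is not an oracle)
  expect_equal(attenuated_correlation(0.707, scheme_5050_left)$rho_censored,
               0.6410821, tolerance = 1e-6)

  # independence and identity preserved
  expect_equal(attenuated_correlation(0, scheme_5050_lr)$rho_censored, 0,
               tolerance = 1e-9)
  none <- censoring_scheme()
  expect_equal(attenuated_correlation(0.63, none)$rho_censored, 0.63,
               tolerance = 1e-8)
})

test_that("quadrature route agrees with the closed form", {
  for (rho in c(-0.95, -0.5, 0.3, 0.8)) {
    expect_equal(
      attenuated_correlation(rho, scheme_5050_left,
                             method = "quadrature")$rho_censored,
      attenuated_correlation(rho, scheme_5050_left,
                             method = "closed_form")$rho_censored,
      tolerance = 1e-6)
  }
})

test_that("attenuation is monotone in the latent correlation", {
  grid <- seq(-1, 1, length.out = 41)
  for (scheme in list(scheme_5050_left,
                      censoring_scheme(left_x = 0.3, left_y = 0.7),
                      censoring_scheme(left_x = 0.25, right_y = 0.6))) {
    vals <- vapply(grid, function(r) {
      attenuated_correlation(r, scheme)$rho_censored
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-8))
    expect_true(all(abs(vals) <= 1))
  }
})

test_that("same-side censoring shrinks |rho| with equality at 0 and 1", {
  for (rho in c(-0.9, -0.4, 0.2, 0.6)) {
    att <- attenuated_correlation(rho, scheme_5050_left)$rho_censored
    expect_lte(abs(att), abs(rho) + 1e-9)
  }
  expect_equal(attenuated_correlation(1, scheme_5050_left)$rho_censored, 1,
               tolerance = 1e-9)
  # opposite sides: equality at -1 instead (the attenuation asymmetry)
  expect_equal(attenuated_correlation(-1, scheme_5050_lr)$rho_censored, -1,
               tolerance = 1e-9)
})

test_that("left/left and right/right schemes attenuate identically", {
  rr <- censoring_scheme(right_x = 0.5, right_y = 0.5)
  for (rho in c(-0.8, -0.3, 0.5, 0.95)) {
    expect_equal(attenuated_correlation(rho, scheme_5050_left)$rho_censored,
                 attenuated_correlation(rho, rr)$rho_censored,
                 tolerance = 1e-7)
  }
  r2 <- censoring_scheme(right_x = 0.3, right_y = 0.3)
  l2 <- censoring_scheme(left_x = 0.3, left_y = 0.3)
  for (rho in c(-0.6, 0.4)) {
    expect_equal(attenuated_correlation(rho, l2)$rho_censored,
                 attenuated_correlation(rho, r2)$rho_censored,
                 tolerance = 1e-7)
  }
})

test_that("mirroring swaps sides, negates thresholds, preserves attenuation", {
  s <- censoring_scheme(left_x = 0.5, left_y = 0.5)
  m <- mirror_scheme(s)
  expect_identical(m$x$right$type, "fraction")
  expect_identical(m$x$right$value, 0.5)
  expect_identical(m$x$left$type, "none")

  none <- censoring_scheme()
  expect_identical(mirror_scheme(none), none)

  thr <- censoring_scheme(lower_x = 0.001, upper_y = 55)
  mt <- mirror_scheme(thr)
  expect_equal(mt$x$right$value, -0.001)
  expect_equal(mt$y$left$value, -55)

  # mirroring both variables leaves rho_xy unchanged
  s2 <- censoring_scheme(left_x = 0.3, left_y = 0.7)
  for (rho in c(-0.7, 0.2, 0.9)) {
    expect_equal(attenuated_correlation(rho, s2)$rho_censored,
                 attenuated_correlation(rho, mirror_scheme(s2))$rho_censored,
                 tolerance = 1e-7)
  }
  # mirroring one variable negates both rho and rho_xy
  lr <- mirror_scheme(s2, variables = "y")
  for (rho in c(-0.8, 0.1, 0.6)) {
    expect_equal(attenuated_correlation(rho, lr)$rho_censored,
                 -attenuated_correlation(-rho, s2)$rho_censored,
                 tolerance = 1e-7)
  }
})

test_that("degenerate and invalid schemes are rejected", {
  expect_error(censoring_scheme(left_x = 0.6, right_x = 0.5),
               "fully censored")
  expect_error(censoring_scheme(left_x = 1), "\\[0, 1\\)")
  expect_error(attenuated_correlation(1.2, scheme_5050_left))
  expect_error(attenuated_correlation(0.5, scheme_5050_left,
                                      method = "closed_form"), NA)
  expect_error(
    attenuated_correlation(0.5, censoring_scheme(left_x = 0.3),
                           method = "closed_form"),
    "closed form")
})

test_that("location and scale of the latent model do not change rho_xy", {
  s <- censoring_scheme(left_x = 0.4, left_y = 0.6)
  base <- censored_moments(bvn_model(rho = 0.6), s)
  shifted <- censored_moments(bvn_model(mu_x = 3, mu_y = -2,
                                        sigma_x = 2.5, sigma_y = 0.4,
                                        rho = 0.6), s)
  rho_of <- function(m) {
    (m$e_xy - m$e_x * m$e_y) /
      sqrt((m$e_x2 - m$e_x^2) * (m$e_y2 - m$e_y^2))
  }
  expect_equal(rho_of(base), rho_of(shifted), tolerance = 1e-7)
})

test_that("bivariate rectangle probabilities match a nested oracle", {
  nested <- function(h, k, r) {
    inner <- function(t) {
      vapply(t, function(ti) {
        integrate(function(u) dbvnorm(rep(ti, length(u)), u,
                                      bvn_model(rho = r)),
                  -Inf, k, rel.tol = 1e-10)$value
      }, numeric(1))
    }
    integrate(inner, -Inf, h, rel.tol = 1e-9)$value
  }
  cases <- list(c(0, 0, 0.5), c(-1, 0.5, -0.8), c(1.2, -0.4, 0.3))
  for (cs in cases) {
    expect_equal(pbvnorm(cs[1], cs[2], cs[3]),
                 nested(cs[1], cs[2], cs[3]), tolerance = 1e-7)
  }
  expect_equal(pbvnorm(0, 0, 0), 0.25, tolerance = 1e-10)
  expect_equal(pbvnorm(0.3, 0.8, 1), pnorm(0.3), tolerance = 1e-12)
  expect_equal(pbvnorm(0.3, -0.3, -1), 0, tolerance = 1e-12)
  expect_equal(pbvnorm(1, 0.5, -1), pnorm(1) + pnorm(0.5) - 1,
               tolerance = 1e-12)
})
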