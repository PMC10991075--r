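#' Correlation implied by the angle between two variables
#'
#' For zero-centred variables the Pearson correlation equals the cosine
#' of the angle between them, so a geometric description of "how
#' opposite" two constructs are translates directly into a latent
#' correlation.
#'
#' @param theta_degrees Angle in degrees (finite scalar or vector).
#' @return `cos(theta)`, in \[-1, 1\].
#' @examples
#' rho_from_angle(c(0, 90, 135, 180))   #  1, 0, -.707, -1
#' @export
rho_from_angle <- function(theta_degrees) {
  if (!is.numeric(theta_degrees) || any(!is.finite(theta_degrees))) {
    stop("angle must be finite", call. = FALSE)
  }
  cos(theta_degrees * pi / 180)
}

#' Moments of a censored bivariate normal pair
#'
#' Censoring clamps each latent variable to its detection limits:
#' x = min(max(X, a), b).  This computes the first two univariate
#' moments of the clamped variables in closed form (normal partial
#' moments) and the cross moment E\[xy\] by reducing the double integral
#' to a one-dimensional adaptive quadrature over x, split at the kinks
#' introduced by the limits.  Degenerate |rho| ~ 1 is routed through the
#' one-dimensional pushforward Y = sign(rho) X.
#'
#' @param model A [bvn_model()].
#' @param scheme A [censoring_scheme()]; fraction sides resolve to
#'   population quantiles of the model marginals.
#' @return A list of class `"censored_moments"` with fields
#'   `e_x`, `e_x2`, `e_y`, `e_y2`, `e_xy` (on the data scale) and the
#'   standardized limits used.
#' @export
censored_moments <- function(model, scheme) {
  lim <- scheme_limits(scheme, model)
  # standardized limits
  ax <- (lim$x[["lower"]] - model$mu_x) / model$sigma_x
  bx <- (lim$x[["upper"]] - model$mu_x) / model$sigma_x
  ay <- (lim$y[["lower"]] - model$mu_y) / model$sigma_y
  by <- (lim$y[["upper"]] - model$mu_y) / model$sigma_y
  r <- model$rho

  m1x <- clamped_normal_m1(ax, bx)
  m2x <- clamped_normal_m2(ax, bx)
  m1y <- clamped_normal_m1(ay, by)
  m2y <- clamped_normal_m2(ay, by)
  mxy <- clamped_cross_moment(r, ax, bx, ay, by)

  # back to the data scale: x = mu + sigma * cz
  e_x <- model$mu_x + model$sigma_x * m1x
  e_y <- model$mu_y + model$sigma_y * m1y
  e_x2 <- model$mu_x^2 + 2 * model$mu_x * model$sigma_x * m1x +
    model$sigma_x^2 * m2x
  e_y2 <- model$mu_y^2 + 2 * model$mu_y * model$sigma_y * m1y +
    model$sigma_y^2 * m2y
  e_xy <- model$mu_x * model$mu_y +
    model$mu_x * model$sigma_y * m1y + model$mu_y * model$sigma_x * m1x +
    model$sigma_x * model$sigma_y * mxy

  structure(
    list(e_x = e_x, e_x2 = e_x2, e_y = e_y, e_y2 = e_y2, e_xy = e_xy,
         z_limits = list(x = c(ax, bx), y = c(ay, by))),
    class = "censored_moments"
  )
}

# E[clamp(Z, a, b)] for standard normal Z; a may be -Inf, b may be Inf.
clamped_normal_m1 <- function(a, b) {
  lo <- if (is.finite(a)) a * stats::pnorm(a) else 0
  hi <- if (is.finite(b)) b * stats::pnorm(b, lower.tail = FALSE) else 0
  lo + (stats::dnorm(a) - stats::dnorm(b)) + hi
}

# E[clamp(Z, a, b)^2]
clamped_normal_m2 <- function(a, b) {
  lo <- if (is.finite(a)) a^2 * stats::pnorm(a) else 0
  hi <- if (is.finite(b)) b^2 * stats::pnorm(b, lower.tail = FALSE) else 0
  mid <- stats::pnorm(b) - stats::pnorm(a) +
    (if (is.finite(a)) a * stats::dnorm(a) else 0) -
    (if (is.finite(b)) b * stats::dnorm(b) else 0)
  lo + mid + hi
}

# E[clamp(Zx, ax, bx) * clamp(Zy, ay, by)] for standard bivariate normal
# with correlation r, by 1-D reduction over zx.
clamped_cross_moment <- function(r, ax, bx, ay, by, tol = 1e-10) {
  if (abs(r) > 1 - 1e-9) {
    # degenerate pushforward: Zy = sign(r) * Zx
    sgn <- sign(r)
    f <- function(x) {
      stats::dnorm(x) * pmin(pmax(x, ax), bx) *
        pmin(pmax(sgn * x, ay), by)
    }
    return(integrate_piecewise(f, c(ax, bx, sgn * ay, sgn * by), tol))
  }
  s <- sqrt(1 - r^2)
  # E[clamp(Zy) | Zx = x]
  ey_given <- function(x) {
    mu <- r * x
    u1 <- (ay - mu) / s
    u2 <- (by - mu) / s
    lo <- if (is.finite(ay)) ay * stats::pnorm(u1) else 0
    hi <- if (is.finite(by)) by * stats::pnorm(u2, lower.tail = FALSE) else 0
    mid <- mu * (stats::pnorm(u2) - stats::pnorm(u1)) +
      s * (stats::dnorm(u1) - stats::dnorm(u2))
    lo + mid + hi
  }
  f <- function(x) stats::dnorm(x) * pmin(pmax(x, ax), bx) * ey_given(x)
  integrate_piecewise(f, c(ax, bx), tol)
}

# Adaptive quadrature over the real line, split at finite kink points.
integrate_piecewise <- function(f, kinks, tol) {
  pts <- sort(unique(kinks[is.finite(kinks)]))
  bounds <- c(-Inf, pts, Inf)
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    total <- total + stats::integrate(
      f, bounds[i], bounds[i + 1L],
      rel.tol = tol, abs.tol = 1e-12, stop.on.error = TRUE)$value
  }
  total
}

#' Closed-form cross moment under 50/50 left censoring
#'
#' For standard bivariate normal (X, Y) with correlation `rho`, both
#' clamped at zero from below (50% left censoring),
#' E\[xy\] = (sqrt(1 - rho^2) + rho (pi/2 + asin rho)) / (2 pi).
#'
#' @param rho Latent correlation.
#' @return E\[max(X,0) max(Y,0)\].
#' @keywords internal
halfnormal_cross_moment <- function(rho) {
  (sqrt(pmax(0, 1 - rho^2)) + rho * (pi / 2 + asin(rho))) / (2 * pi)
}

#' Attenuated correlation between censored variables
#'
#' Computes the population correlation between the censored pair (x, y)
#' implied by a latent standard bivariate normal correlation and a
#' censoring scheme.  Censoring generally shrinks the correlation toward
#' zero, asymmetrically: same-side censoring (both floors, or both
#' ceilings) distorts negative correlations more, opposite-side
#' censoring distorts positive correlations more.
#'
#' When every censored side is a 50% fraction the half-normal closed
#' form is used; otherwise the moments are obtained by quadrature
#' ([censored_moments()]).  `method = "monte_carlo"` delegates to the
#' simulator [censorcorr()].
#'
#' @param rho_latent Latent correlation, in \[-1, 1\].
#' @param scheme A [censoring_scheme()] (fractions interpreted as
#'   population fractions; thresholds are on the standard-normal scale).
#' @param method `"auto"` (closed form when available, else
#'   quadrature), `"closed_form"`, `"quadrature"`, or `"monte_carlo"`.
#' @param n,seed Monte-Carlo sample size and seed (only used for
#'   `method = "monte_carlo"`).
#' @return An object of class `"attenuation_result"`: a list with
#'   `rho_latent`, `rho_censored`, `scheme`, `method`, and
#'   `mc_standard_error` (`NA` unless Monte Carlo).
#'
#' @examples
#' s <- censoring_scheme(left_x = 0.5, left_y = 0.5)
#' attenuated_correlation(-1, s)$rho_censored      # -0.467
#' attenuated_correlation(-0.707, s)$rho_censored  # -0.396
#' @export
attenuated_correlation <- function(rho_latent, scheme,
                                   method = c("auto", "closed_form",
                                              "quadrature", "monte_carlo"),
                                   n = 500000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(rho_latent), length(rho_latent) == 1L,
            is.finite(rho_latent))
  if (abs(rho_latent) > 1) stop("|rho| must be <= 1", call. = FALSE)
  scheme_limits(scheme)  # validates total censoring

  if (method == "monte_carlo") {
    return(censorcorr(rho_latent, scheme, n = n, seed = seed))
  }

  cf <- closed_form_signature(scheme)
  if (method == "closed_form" && is.null(cf)) {
    stop("closed form only available for 50% one-sided censoring on both variables",
         call. = FALSE)
  }
  if (!is.null(cf) && method %in% c("auto", "closed_form")) {
    # Map to the canonical both-left case by sign flips: censoring the
    # sign-flipped variable on the left equals censoring the original on
    # the right, and flipping one variable negates the correlation.
    flip <- cf$flip_x * cf$flip_y
    rho_c <- flip * halfnormal_rho_xy(flip * rho_latent)
    used <- "closed_form"
  } else {
    mom <- censored_moments(bvn_model(rho = rho_latent), scheme)
    vx <- mom$e_x2 - mom$e_x^2
    vy <- mom$e_y2 - mom$e_y^2
    if (vx <= 0 || vy <= 0) stop("variable fully censored", call. = FALSE)
    rho_c <- (mom$e_xy - mom$e_x * mom$e_y) / sqrt(vx * vy)
    used <- "quadrature"
  }
  structure(
    list(rho_latent = rho_latent,
         rho_censored = max(-1, min(1, rho_c)),
         scheme = scheme, method = used,
         mc_standard_error = NA_real_),
    class = "attenuation_result"
  )
}

# rho_xy under 50/50 left censoring on both variables (standard normal):
# moments E[x] = sqrt(1/(2 pi)), E[x^2] = 1/2 of the half normal.
halfnormal_rho_xy <- function(rho) {
  (halfnormal_cross_moment(rho) - 1 / (2 * pi)) / (0.5 - 1 / (2 * pi))
}

# If the scheme is 50% fraction censoring on exactly one side of each
# variable, return the sign flips mapping it to both-left; else NULL.
closed_form_signature <- function(scheme) {
  one <- function(v) {
    l <- scheme[[v]]$left; r <- scheme[[v]]$right
    if (l$type == "fraction" && l$value == 0.5 && r$type == "none") return(1)
    if (r$type == "fraction" && r$value == 0.5 && l$type == "none") return(-1)
    NULL
  }
  fx <- one("x"); fy <- one("y")
  if (is.null(fx) || is.null(fy)) return(NULL)
  list(flip_x = fx, flip_y = fy)
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf("Attenuated correlation (%s)\n", x$method))
  cat(sprintf("  latent rho = %.3f  ->  censored rho = %.3f\n",
              x$rho_latent, x$rho_censored))
  if (is.finite(x$mc_standard_error)) {
    cat(sprintf("  Monte-Carlo standard error ~ %.2g\n", x$mc_standard_error))
  }
  invisible(x)
}
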