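#' Latent bivariate normal model
#'
#' Describes the joint distribution of the *uncensored* pair (X, Y):
#' marginal means and standard deviations plus the latent correlation
#' `rho`.  This is the distribution censoring acts on; all attenuation
#' and likelihood computations in the package refer back to it.
#'
#' @param mu_x,mu_y Marginal means.
#' @param sigma_x,sigma_y Marginal standard deviations (must be positive).
#' @param rho Latent correlation, in \[-1, 1\].
#'
#' @return An object of class `"bvn_model"`: a list with fields
#'   `mu_x`, `mu_y`, `sigma_x`, `sigma_y`, `rho`.
#'
#' @examples
#' bvn_model(rho = 0.7)
#' bvn_model(mu_x = 10, sigma_x = 2, rho = -0.5)
#' @export
bvn_model <- function(mu_x = 0, mu_y = 0, sigma_x = 1, sigma_y = 1, rho = 0) {
  stopifnot(
    is.numeric(mu_x), length(mu_x) == 1L, is.finite(mu_x),
    is.numeric(mu_y), length(mu_y) == 1L, is.finite(mu_y),
    is.numeric(sigma_x), length(sigma_x) == 1L, is.finite(sigma_x),
    is.numeric(sigma_y), length(sigma_y) == 1L, is.finite(sigma_y),
    is.numeric(rho), length(rho) == 1L, is.finite(rho)
  )
  if (sigma_x <= 0 || sigma_y <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  if (abs(rho) > 1) {
    stop("rho must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(mu_x = mu_x, mu_y = mu_y,
         sigma_x = sigma_x, sigma_y = sigma_y, rho = rho),
    class = "bvn_model"
  )
}

#' @export
print.bvn_model <- function(x, ...) {
  cat("Bivariate normal model\n")
  cat(sprintf("  X ~ N(%g, %g^2)   Y ~ N(%g, %g^2)   rho = %g\n",
              x$mu_x, x$sigma_x, x$mu_y, x$sigma_y, x$rho))
  invisible(x)
}

#' Bivariate normal density
#'
#' Density of the latent pair at (x, y).  Requires |rho| < 1; the
#' degenerate perfectly correlated case has no joint density.
#'
#' @param x,y Numeric vectors (recycled to common length).
#' @param model A [bvn_model()].
#' @param log Return the log density?
#' @return Numeric vector of (log) densities.
#' @export
dbvnorm <- function(x, y, model, log = FALSE) {
  r <- model$rho
  if (abs(r) >= 1) stop("density undefined at |rho| = 1", call. = FALSE)
  zx <- (x - model$mu_x) / model$sigma_x
  zy <- (y - model$mu_y) / model$sigma_y
  om <- 1 - r^2
  ld <- -log(2 * pi) - log(model$sigma_x) - log(model$sigma_y) -
    0.5 * log(om) - (zx^2 - 2 * r * zx * zy + zy^2) / (2 * om)
  if (log) ld else exp(ld)
}

#' Bivariate normal rectangle probability
#'
#' Computes P(X <= h, Y <= k) for standard bivariate normal (X, Y) with
#' correlation `rho`, by adaptive one-dimensional quadrature of
#' `dnorm(t) * pnorm((k - rho * t) / sqrt(1 - rho^2))`.  The degenerate
#' boundaries rho = 1 (comonotone) and rho = -1 (antithetic) are handled
#' by their exact limits.
#'
#' @param h,k Upper integration limits (scalars; `Inf` allowed).
#' @param rho Correlation in \[-1, 1\].
#' @return The rectangle probability, a scalar in \[0, 1\].
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(h) == 1L, length(k) == 1L, length(rho) == 1L,
            !is.na(h), !is.na(k), is.finite(rho), abs(rho) <= 1)
  if (h == -Inf || k == -Inf) return(0)
  if (h == Inf) return(stats::pnorm(k))
  if (k == Inf) return(stats::pnorm(h))
  if (rho >= 1) return(stats::pnorm(min(h, k)))
  if (rho <= -1) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  s <- sqrt(1 - rho^2)
  f <- function(t) stats::dnorm(t) * stats::pnorm((k - rho * t) / s)
  stats::integrate(f, -Inf, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}
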