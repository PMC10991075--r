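#' Log-likelihood of a censored bivariate normal sample
#'
#' Tobit-type full-information likelihood.  Each pair contributes
#' according to its censoring pattern:
#' \itemize{
#'   \item both observed: the bivariate normal log density;
#'   \item one censored (say x left-censored at a, y observed): the
#'     marginal density of y times the conditional normal tail
#'     probability P(X <= a | Y = y), using the conditional mean
#'     mu_x + rho (sigma_x / sigma_y)(y - mu_y) and standard deviation
#'     sigma_x sqrt(1 - rho^2); right censoring uses the upper tail;
#'   \item both censored: the bivariate normal rectangle probability of
#'     the censored quadrant.
#' }
#' At |rho| = 1 the likelihood of any censored observation degenerates;
#' `-Inf` is returned rather than an error.
#'
#' @param model A [bvn_model()].
#' @param sample A [censored_sample()].
#' @return The log-likelihood (scalar; may be `-Inf`).
#' @export
loglik_censored <- function(model, sample) {
  stopifnot(inherits(sample, "censored_sample"), sample$n >= 1L)
  r <- model$rho
  if (abs(r) >= 1) return(-Inf)
  sx <- model$sigma_x; sy <- model$sigma_y
  zx <- (sample$x - model$mu_x) / sx
  zy <- (sample$y - model$mu_y) / sy
  s <- sqrt(1 - r^2)

  xs <- sample$x_status; ys <- sample$y_status
  ll <- 0

  oo <- xs == "obs" & ys == "obs"
  if (any(oo)) {
    q <- (zx[oo]^2 - 2 * r * zx[oo] * zy[oo] + zy[oo]^2) / (2 * (1 - r^2))
    ll <- ll + sum(-log(2 * pi) - log(sx) - log(sy) - 0.5 * log(1 - r^2) - q)
  }

  # x censored, y observed: f(y) * tail of X | Y = y
  cx <- xs != "obs" & ys == "obs"
  if (any(cx)) {
    u <- (zx[cx] - r * zy[cx]) / s
    lower <- xs[cx] == "left"
    tail_lp <- stats::pnorm(u, lower.tail = TRUE, log.p = TRUE)
    tail_up <- stats::pnorm(u, lower.tail = FALSE, log.p = TRUE)
    ll <- ll + sum(stats::dnorm(zy[cx], log = TRUE) - log(sy) +
                     ifelse(lower, tail_lp, tail_up))
  }

  # y censored, x observed
  cy <- ys != "obs" & xs == "obs"
  if (any(cy)) {
    u <- (zy[cy] - r * zx[cy]) / s
    lower <- ys[cy] == "left"
    tail_lp <- stats::pnorm(u, lower.tail = TRUE, log.p = TRUE)
    tail_up <- stats::pnorm(u, lower.tail = FALSE, log.p = TRUE)
    ll <- ll + sum(stats::dnorm(zx[cy], log = TRUE) - log(sx) +
                     ifelse(lower, tail_lp, tail_up))
  }

  # both censored: rectangle probabilities, computed once per distinct
  # (status, limit) combination -- censored values all sit at the limits
  cc <- xs != "obs" & ys != "obs"
  if (any(cc)) {
    key <- paste(xs[cc], ys[cc], zx[cc], zy[cc])
    for (k in unique(key)) {
      idx <- which(cc)[key == k]
      i <- idx[1L]
      p <- rect_prob(zx[i], zy[i], r, xs[i], ys[i])
      if (p <= 0) return(-Inf)
      ll <- ll + length(idx) * log(p)
    }
  }
  ll
}

# P(X in censored region, Y in censored region) for standard bivariate
# normal; h, k are the standardized limits, side is "left" or "right".
rect_prob <- function(h, k, r, side_x, side_y) {
  if (side_x == "left" && side_y == "left") {
    pbvnorm(h, k, r)
  } else if (side_x == "left" && side_y == "right") {
    stats::pnorm(h) - pbvnorm(h, k, r)
  } else if (side_x == "right" && side_y == "left") {
    stats::pnorm(k) - pbvnorm(h, k, r)
  } else {
    1 - stats::pnorm(h) - stats::pnorm(k) + pbvnorm(h, k, r)
  }
}

# Gradient of loglik_censored with respect to
# (mu_x, mu_y, sigma_x, sigma_y, rho), on the natural scale.
grad_loglik_model <- function(model, sample) {
  r <- model$rho
  if (abs(r) >= 1) return(rep(NA_real_, 5L))
  sx <- model$sigma_x; sy <- model$sigma_y
  zx <- (sample$x - model$mu_x) / sx
  zy <- (sample$y - model$mu_y) / sy
  s2 <- 1 - r^2
  s <- sqrt(s2)
  xs <- sample$x_status; ys <- sample$y_status
  g <- numeric(5L)  # mu_x, mu_y, sigma_x, sigma_y, rho

  oo <- xs == "obs" & ys == "obs"
  if (any(oo)) {
    a <- zx[oo]; b <- zy[oo]
    A <- (a - r * b) / s2
    B <- (b - r * a) / s2
    Q <- (a^2 - 2 * r * a * b + b^2) / s2
    g[1L] <- g[1L] + sum(A) / sx
    g[2L] <- g[2L] + sum(B) / sy
    g[3L] <- g[3L] + sum(A * a - 1) / sx
    g[4L] <- g[4L] + sum(B * b - 1) / sy
    g[5L] <- g[5L] + sum(r / s2 + a * b / s2 - r * Q / s2)
  }

  # inverse Mills ratio of the censored tail, on the log scale
  lam <- function(u, left) {
    cc <- ifelse(left, 1, -1)
    cc * exp(stats::dnorm(u, log = TRUE) -
               stats::pnorm(cc * u, log.p = TRUE))
  }

  cx <- xs != "obs" & ys == "obs"
  if (any(cx)) {
    a <- zx[cx]; b <- zy[cx]
    u <- (a - r * b) / s
    l <- lam(u, xs[cx] == "left")
    g[1L] <- g[1L] + sum(-l / (s * sx))
    g[2L] <- g[2L] + sum(b / sy + l * r / (s * sy))
    g[3L] <- g[3L] + sum(-l * a / (s * sx))
    g[4L] <- g[4L] + sum((b^2 - 1) / sy + l * r * b / (s * sy))
    g[5L] <- g[5L] + sum(l * (r * a - b) / s^3)
  }

  cy <- ys != "obs" & xs == "obs"
  if (any(cy)) {
    a <- zy[cy]; b <- zx[cy]
    u <- (a - r * b) / s
    l <- lam(u, ys[cy] == "left")
    g[2L] <- g[2L] + sum(-l / (s * sy))
    g[1L] <- g[1L] + sum(b / sx + l * r / (s * sx))
    g[4L] <- g[4L] + sum(-l * a / (s * sy))
    g[3L] <- g[3L] + sum((b^2 - 1) / sx + l * r * b / (s * sx))
    g[5L] <- g[5L] + sum(l * (r * a - b) / s^3)
  }

  cc <- xs != "obs" & ys != "obs"
  if (any(cc)) {
    key <- paste(xs[cc], ys[cc], zx[cc], zy[cc])
    for (k in unique(key)) {
      idx <- which(cc)[key == k]
      i <- idx[1L]
      h <- zx[i]; kk <- zy[i]
      sgx <- if (xs[i] == "left") 1 else -1
      sgy <- if (ys[i] == "left") 1 else -1
      P <- rect_prob(h, kk, r, xs[i], ys[i])
      if (P <= 0) return(rep(NA_real_, 5L))
      # conditional probability of the y region given X = h, and vice versa
      py_h <- stats::pnorm(sgy * (kk - r * h) / s)
      px_k <- stats::pnorm(sgx * (h - r * kk) / s)
      dPdh <- sgx * stats::dnorm(h) * py_h
      dPdk <- sgy * stats::dnorm(kk) * px_k
      dens <- exp(-(h^2 - 2 * r * h * kk + kk^2) / (2 * s2)) / (2 * pi * s)
      dPdr <- sgx * sgy * dens
      m <- length(idx)
      g[1L] <- g[1L] + m * (dPdh / P) * (-1 / sx)
      g[2L] <- g[2L] + m * (dPdk / P) * (-1 / sy)
      g[3L] <- g[3L] + m * (dPdh / P) * (-h / sx)
      g[4L] <- g[4L] + m * (dPdk / P) * (-kk / sy)
      g[5L] <- g[5L] + m * dPdr / P
    }
  }
  g
}

grad_neg_loglik_theta <- function(theta, sample, parameterization) {
  m <- theta_to_model(theta, parameterization)
  if (!is.finite(m$sigma_x) || !is.finite(m$sigma_y) ||
      m$sigma_x <= 0 || m$sigma_y <= 0 || !is.finite(m$rho) ||
      abs(m$rho) >= 1) {
    return(rep(0, 5L))
  }
  g <- grad_loglik_model(m, sample)
  if (any(!is.finite(g))) return(rep(0, 5L))
  # chain rule to the working scale: log sigmas, and atanh(rho) if
  # constrained
  g[3L] <- g[3L] * m$sigma_x
  g[4L] <- g[4L] * m$sigma_y
  if (parameterization == "constrained") g[5L] <- g[5L] * (1 - m$rho^2)
  -g
}

# parameter vector <-> model; g is rho (unconstrained) or atanh(rho)
theta_to_model <- function(theta, parameterization) {
  rho <- if (parameterization == "constrained") tanh(theta[5L]) else theta[5L]
  list(mu_x = theta[1L], mu_y = theta[2L],
       sigma_x = exp(theta[3L]), sigma_y = exp(theta[4L]), rho = rho)
}

neg_loglik_theta <- function(theta, sample, parameterization) {
  m <- theta_to_model(theta, parameterization)
  if (!is.finite(m$sigma_x) || !is.finite(m$sigma_y) ||
      m$sigma_x <= 0 || m$sigma_y <= 0 || !is.finite(m$rho) ||
      abs(m$rho) >= 1) {
    return(1e10)
  }
  ll <- loglik_censored(structure(m, class = "bvn_model"), sample)
  if (!is.finite(ll)) 1e10 else -ll
}

#' Fit the censored bivariate normal model by maximum likelihood
#'
#' Maximizes [loglik_censored()] over (mu_x, mu_y, log sigma_x,
#' log sigma_y, g) with a quasi-Newton search (`nlminb`).  Two
#' parameterizations of the correlation are offered: `"unconstrained"`
#' optimizes rho directly (the analogue of fitting an unrestricted
#' covariance, which can fail or wander to the boundary), and
#' `"constrained"` optimizes g = atanh(rho), which guarantees a valid
#' correlation strictly inside (-1, 1) -- the analogue of constraining
#' the covariance matrix to be positive definite.
#'
#' @param sample A [censored_sample()] with at least 5 cases and at
#'   least one observed value on each variable.  Fully observed pairs
#'   are not required: under heavy censoring of a strongly correlated
#'   pair, complete pairs can be vanishingly rare, yet the correlation
#'   remains identified through the single-censored tail
#'   contributions.
#' @param parameterization `"constrained"` (default, recommended) or
#'   `"unconstrained"`.
#' @param start Optional [bvn_model()] of starting values; by default
#'   moments of the censored data (means, SDs, Pearson r).
#' @param control Passed to [stats::nlminb()]; defaults set
#'   `abs.tol = 1e-8` on the objective and 500 iterations.
#' @return An object of class `"cbn_fit"`: `model_hat` (a
#'   [bvn_model()]), `loglik`, `converged`, `invalid` (unconstrained
#'   optimum outside \[-1, 1\]), `parameterization`, `se_rho` (filled
#'   by [wald_ci()]), `n_evals`, `messages`, `theta` (working-scale
#'   optimum), and the `sample` size `n`.
#'
#' @examples
#' set.seed(42)
#' d <- sample_latent(bvn_model(rho = 0.7), 200)
#' cs <- censor_sample(d$x, d$y, censoring_scheme(left_x = .5, left_y = .5))
#' fit_censored(cs)$model_hat$rho
#' @export
fit_censored <- function(sample,
                         parameterization = c("constrained", "unconstrained"),
                         start = NULL, control = list()) {
  parameterization <- match.arg(parameterization)
  stopifnot(inherits(sample, "censored_sample"))
  if (sample$n < 5L) stop("need at least 5 cases", call. = FALSE)
  if (all(sample$x_status != "obs") || all(sample$y_status != "obs")) {
    stop("unidentified: one variable entirely censored", call. = FALSE)
  }

  if (is.null(start)) {
    r0 <- suppressWarnings(stats::cor(sample$x, sample$y))
    if (!is.finite(r0)) r0 <- 0
    r0 <- max(-0.95, min(0.95, r0))
    start <- list(mu_x = mean(sample$x), mu_y = mean(sample$y),
                  sigma_x = max(stats::sd(sample$x), 1e-3),
                  sigma_y = max(stats::sd(sample$y), 1e-3),
                  rho = r0)
  }
  g0 <- if (parameterization == "constrained") atanh(start$rho) else start$rho
  theta0 <- c(start$mu_x, start$mu_y,
              log(start$sigma_x), log(start$sigma_y), g0)

  ctrl <- utils::modifyList(
    list(abs.tol = 1e-8, rel.tol = 1e-12, x.tol = 1e-11,
         iter.max = 500, eval.max = 2000),
    control)
  opt <- tryCatch(
    stats::nlminb(theta0, neg_loglik_theta,
                  gradient = grad_neg_loglik_theta, sample = sample,
                  parameterization = parameterization, control = ctrl),
    error = function(e) NULL)

  if (is.null(opt)) {
    return(structure(
      list(model_hat = NULL, loglik = NA_real_, converged = FALSE,
           invalid = FALSE, parameterization = parameterization,
           se_rho = NA_real_, n_evals = 0L,
           messages = "optimizer error", theta = NULL, n = sample$n),
      class = "cbn_fit"))
  }

  m <- theta_to_model(opt$par, parameterization)
  invalid <- parameterization == "unconstrained" && abs(m$rho) > 1
  # nlminb's return code can flag "singular"/"false" convergence at a
  # genuine optimum under tight step tolerances; accept the fit when
  # the score is numerically zero there
  grad_ok <- FALSE
  if (is.finite(opt$objective) && opt$objective < 1e9) {
    g <- grad_neg_loglik_theta(opt$par, sample, parameterization)
    grad_ok <- all(is.finite(g)) && max(abs(g)) < 1e-2
  }
  converged <- (opt$convergence == 0 || grad_ok) &&
    is.finite(opt$objective) && opt$objective < 1e9 && !invalid
  structure(
    list(model_hat = bvn_model(m$mu_x, m$mu_y, m$sigma_x, m$sigma_y,
                               max(-1, min(1, m$rho))),
         loglik = -opt$objective, converged = converged, invalid = invalid,
         parameterization = parameterization, se_rho = NA_real_,
         n_evals = sum(opt$evaluations), messages = opt$message,
         theta = opt$par, n = sample$n),
    class = "cbn_fit")
}

#' @export
print.cbn_fit <- function(x, ...) {
  cat(sprintf("Censored bivariate normal ML fit (%s)\n", x$parameterization))
  if (is.null(x$model_hat)) {
    cat("  did not converge:", x$messages, "\n")
    return(invisible(x))
  }
  cat(sprintf("  rho_hat = %.4f  loglik = %.3f  converged = %s\n",
              x$model_hat$rho, x$loglik, x$converged))
  invisible(x)
}

#' Wald confidence interval for the latent correlation
#'
#' Standard errors come from the observed information (numerical Hessian
#' of the log-likelihood at the optimum, central differences).  For the
#' unconstrained fit the interval is built directly on the rho scale and
#' may exceed +/-1 (reported as-is); for the constrained fit it is built
#' on the atanh scale and mapped through tanh, so it always lies inside
#' (-1, 1).
#'
#' @param fit A converged [fit_censored()] result.
#' @param sample The [censored_sample()] the fit was computed from.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"cbn_ci"`: `lower`, `upper`, `level`,
#'   `method` (`"wald_unconstrained"` or `"wald_constrained"`),
#'   `converged`, `midpoint`, `width`, `se_rho` (delta-method SE on the
#'   rho scale).
#' @export
wald_ci <- function(fit, sample, level = 0.95) {
  stopifnot(inherits(fit, "cbn_fit"), level > 0, level < 1)
  method <- paste0("wald_", fit$parameterization)
  fail <- structure(
    list(lower = NA_real_, upper = NA_real_, level = level,
         method = method, converged = FALSE,
         midpoint = NA_real_, width = NA_real_, se_rho = NA_real_),
    class = "cbn_ci")
  if (!fit$converged) return(fail)

  H <- tryCatch(
    stats::optimHess(fit$theta, neg_loglik_theta,
                     gr = grad_neg_loglik_theta, sample = sample,
                     parameterization = fit$parameterization),
    error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(fail)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || !is.finite(V[5L, 5L]) || V[5L, 5L] <= 0) return(fail)
  se_g <- sqrt(V[5L, 5L])
  z <- stats::qnorm((1 + level) / 2)
  g <- fit$theta[5L]
  if (fit$parameterization == "constrained") {
    lower <- tanh(g - z * se_g)
    upper <- tanh(g + z * se_g)
    se_rho <- (1 - tanh(g)^2) * se_g
  } else {
    lower <- g - z * se_g
    upper <- g + z * se_g
    se_rho <- se_g
  }
  structure(
    list(lower = lower, upper = upper, level = level, method = method,
         converged = TRUE, midpoint = (lower + upper) / 2,
         width = upper - lower, se_rho = se_rho),
    class = "cbn_ci")
}

#' Profile-likelihood confidence interval for the latent correlation
#'
#' Inverts the likelihood-ratio test: the endpoints are the rho values
#' at which the profile log-likelihood (all nuisance parameters
#' re-maximized at each fixed rho) has dropped by
#' `qchisq(level, 1) / 2` from its maximum, located by root bracketing
#' and bisection on each side of the estimate.  Endpoints cannot leave
#' (-1, 1); if no crossing is bracketed before the boundary on a side,
#' the interval is clamped there and flagged as not converged.
#'
#' @param fit A converged constrained [fit_censored()] result.
#' @param sample The [censored_sample()] the fit was computed from.
#' @param level Confidence level (default 0.95).
#' @return A `"cbn_ci"` with `method = "profile"`.
#' @export
profile_ci <- function(fit, sample, level = 0.95) {
  stopifnot(inherits(fit, "cbn_fit"), level > 0, level < 1)
  fail <- structure(
    list(lower = NA_real_, upper = NA_real_, level = level,
         method = "profile", converged = FALSE,
         midpoint = NA_real_, width = NA_real_, se_rho = NA_real_),
    class = "cbn_ci")
  if (!fit$converged || fit$parameterization != "constrained") return(fail)

  nuis0 <- fit$theta[1:4]
  prof <- function(rho) {
    obj <- function(nu) {
      neg_loglik_theta(c(nu, atanh(rho)), sample, "constrained")
    }
    grd <- function(nu) {
      grad_neg_loglik_theta(c(nu, atanh(rho)), sample, "constrained")[1:4]
    }
    o <- tryCatch(
      stats::nlminb(nuis0, obj, gradient = grd,
                    control = list(abs.tol = 1e-8, iter.max = 300)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective) || o$objective >= 1e9) {
      return(NA_real_)
    }
    -o$objective
  }

  drop <- stats::qchisq(level, df = 1) / 2
  target <- fit$loglik - drop
  rho_hat <- fit$model_hat$rho
  eps <- 1e-9
  step0 <- if (is.finite(fit$se_rho) && fit$se_rho > 0) fit$se_rho else 0.05

  find_side <- function(dir) {
    # dir = -1 for lower endpoint, +1 for upper
    bound <- dir * (1 - eps)
    lo <- rho_hat
    step <- step0
    repeat {
      cand <- rho_hat + dir * step
      if (dir * cand >= dir * bound) cand <- bound
      g <- prof(cand)
      if (is.na(g)) return(list(value = NA_real_, ok = FALSE))
      if (g < target) {
        root <- tryCatch(
          stats::uniroot(function(r) {
            v <- prof(r); if (is.na(v)) -Inf else v - target
          }, lower = min(lo, cand), upper = max(lo, cand),
          tol = 1e-6)$root,
          error = function(e) NA_real_)
        if (is.na(root)) return(list(value = cand, ok = FALSE))
        return(list(value = root, ok = TRUE))
      }
      if (cand == bound) {
        # still above the cutoff at the boundary: clamp, flag
        return(list(value = bound, ok = FALSE))
      }
      lo <- cand
      step <- step * 2
    }
  }

  lo <- find_side(-1)
  hi <- find_side(+1)
  if (is.na(lo$value) || is.na(hi$value)) return(fail)
  structure(
    list(lower = lo$value, upper = hi$value, level = level,
         method = "profile", converged = lo$ok && hi$ok,
         midpoint = (lo$value + hi$value) / 2,
         width = hi$value - lo$value, se_rho = NA_real_),
    class = "cbn_ci")
}

#' @export
print.cbn_ci <- function(x, ...) {
  cat(sprintf("%g%% confidence interval (%s)\n", 100 * x$level, x$method))
  if (!x$converged && is.na(x$lower)) {
    cat("  did not converge\n")
  } else {
    cat(sprintf("  [%.4f, %.4f]  width %.4f%s\n", x$lower, x$upper, x$width,
                if (x$converged) "" else "  (boundary, not converged)"))
  }
  invisible(x)
}
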