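#' Draw a latent bivariate normal sample
#'
#' Generates `n` iid pairs from the model via the conditional
#' construction y = rho * x + sqrt(1 - rho^2) * e, which remains exact
#' at |rho| = 1 (y is then an affine function of x).
#'
#' @param model A [bvn_model()].
#' @param n Sample size (>= 1).
#' @param seed Optional integer seed; if supplied the draw is
#'   reproducible.
#' @return A data frame with numeric columns `x` and `y`.
#' @export
sample_latent <- function(model, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n))
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  r <- model$rho
  x <- model$mu_x + model$sigma_x * z1
  y <- model$mu_y + model$sigma_y * (r * z1 + sqrt(max(0, 1 - r^2)) * z2)
  data.frame(x = x, y = y)
}

#' Censor a vector by fraction or threshold
#'
#' Applies left and/or right censoring to a numeric vector.  In
#' `"sample"` mode (the usual design of censoring simulations) the left
#' threshold is the order statistic at rank `ceiling(p_left * n)` and
#' the lowest `ceiling(p_left * n)` values (ties broken by rank) are
#' replaced by it, so exactly that share of the sample is censored; the
#' right side mirrors this.  In `"population"` mode the thresholds are
#' quantiles of the supplied reference normal and every value at or
#' beyond a threshold is censored.
#'
#' @param values Numeric vector.
#' @param p_left,p_right Censoring fractions, `p_left + p_right < 1`.
#' @param mode `"sample"` or `"population"`.
#' @param mu,sigma Reference normal for population mode.
#' @param lower,upper Optional fixed thresholds (override fractions).
#' @return A list with `values` (censored data), `status` (character,
#'   `"obs"`, `"left"`, `"right"`) and `limits` (`c(lower, upper)`,
#'   `-Inf`/`Inf` where uncensored).
#' @examples
#' apply_censoring(1:10, p_left = 0.3)$values   # 3 3 3 4 ... 10
#' @export
apply_censoring <- function(values, p_left = 0, p_right = 0,
                            mode = c("sample", "population"),
                            mu = 0, sigma = 1,
                            lower = NULL, upper = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), length(values) >= 1L,
            all(is.finite(values)))
  n <- length(values)
  status <- rep("obs", n)
  lims <- c(lower = -Inf, upper = Inf)

  if (is.null(lower) && is.null(upper)) {
    stopifnot(p_left >= 0, p_right >= 0)
    if (p_left + p_right >= 1) {
      stop("p_left + p_right must be < 1", call. = FALSE)
    }
    if ((p_left > 0 || p_right > 0) &&
        length(unique(values)) == 1L) {
      stop("no variation to censor", call. = FALSE)
    }
    if (mode == "sample") {
      ord <- order(values)
      kl <- ceiling(p_left * n)
      if (kl + ceiling(p_right * n) > n) {
        stop("censoring fractions cover the whole sample", call. = FALSE)
      }
      if (kl > 0L) {
        thr <- values[ord[kl]]
        values[ord[seq_len(kl)]] <- thr
        status[ord[seq_len(kl)]] <- "left"
        lims[["lower"]] <- thr
      }
      kr <- ceiling(p_right * n)
      if (kr > 0L) {
        idx <- ord[seq.int(n - kr + 1L, n)]
        thr <- values[ord[n - kr + 1L]]
        values[idx] <- thr
        status[idx] <- "right"
        lims[["upper"]] <- thr
      }
    } else {
      if (p_left > 0) lims[["lower"]] <- stats::qnorm(p_left, mu, sigma)
      if (p_right > 0) lims[["upper"]] <- stats::qnorm(1 - p_right, mu, sigma)
      left <- values <= lims[["lower"]]
      right <- values >= lims[["upper"]]
      values[left] <- lims[["lower"]]; status[left] <- "left"
      values[right] <- lims[["upper"]]; status[right] <- "right"
    }
  } else {
    if (!is.null(lower)) lims[["lower"]] <- lower
    if (!is.null(upper)) lims[["upper"]] <- upper
    if (lims[["lower"]] >= lims[["upper"]]) {
      stop("lower limit must be below upper limit", call. = FALSE)
    }
    left <- values <= lims[["lower"]]
    right <- values >= lims[["upper"]]
    values[left] <- lims[["lower"]]; status[left] <- "left"
    values[right] <- lims[["upper"]]; status[right] <- "right"
  }
  list(values = values, status = status, limits = lims)
}

#' Construct a censored bivariate sample
#'
#' The estimator's input: paired values with per-value censoring status
#' and the detection limits actually used.  Censored values must equal
#' their limit; statuses are `"obs"`, `"left"`, `"right"`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param x_status,y_status Character status vectors.
#' @param x_limits,y_limits Length-2 numeric `c(lower, upper)`
#'   (`-Inf`/`Inf` on uncensored sides).
#' @return An object of class `"censored_sample"`.
#' @export
censored_sample <- function(x, y,
                            x_status = rep("obs", length(x)),
                            y_status = rep("obs", length(y)),
                            x_limits = c(-Inf, Inf),
                            y_limits = c(-Inf, Inf)) {
  n <- length(x)
  stopifnot(length(y) == n, length(x_status) == n, length(y_status) == n,
            is.numeric(x), is.numeric(y),
            length(x_limits) == 2L, length(y_limits) == 2L)
  ok <- c("obs", "left", "right")
  bad <- which(!(x_status %in% ok) | !(y_status %in% ok))
  if (length(bad)) {
    stop(sprintf("invalid status token at row %d", bad[1L]), call. = FALSE)
  }
  check <- function(v, st, lim, name) {
    if (any(st == "left") && !isTRUE(all(v[st == "left"] == lim[1L]))) {
      stop(sprintf("left-censored %s values must equal the lower limit", name),
           call. = FALSE)
    }
    if (any(st == "right") && !isTRUE(all(v[st == "right"] == lim[2L]))) {
      stop(sprintf("right-censored %s values must equal the upper limit", name),
           call. = FALSE)
    }
    obs <- v[st == "obs"]
    if (length(obs) && (any(obs < lim[1L]) || any(obs > lim[2L]))) {
      stop(sprintf("observed %s values outside the detection limits", name),
           call. = FALSE)
    }
  }
  check(x, x_status, x_limits, "x")
  check(y, y_status, y_limits, "y")
  structure(
    list(n = n, x = as.numeric(x), y = as.numeric(y),
         x_status = x_status, y_status = y_status,
         x_limits = as.numeric(x_limits), y_limits = as.numeric(y_limits)),
    class = "censored_sample"
  )
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Censored sample: n = %d\n", x$n))
  cat(sprintf("  x: %d obs, %d left, %d right\n",
              sum(x$x_status == "obs"), sum(x$x_status == "left"),
              sum(x$x_status == "right")))
  cat(sprintf("  y: %d obs, %d left, %d right\n",
              sum(x$y_status == "obs"), sum(x$y_status == "left"),
              sum(x$y_status == "right")))
  invisible(x)
}

#' Apply a censoring scheme to paired data
#'
#' Convenience wrapper: censors `x` and `y` according to the scheme's
#' fractions/thresholds and assembles a [censored_sample()].
#'
#' @param x,y Numeric vectors of equal length.
#' @param scheme A [censoring_scheme()].
#' @param mode `"sample"` (percentile of the data, the simulation-study
#'   rule) or `"population"` (quantile of the reference marginals).
#' @param model Reference [bvn_model()] for population quantiles.
#' @return A [censored_sample()].
#' @export
censor_sample <- function(x, y, scheme, mode = c("sample", "population"),
                          model = bvn_model()) {
  mode <- match.arg(mode)
  one <- function(v, values, mu, sigma) {
    l <- scheme[[v]]$left; r <- scheme[[v]]$right
    if (l$type == "threshold" || r$type == "threshold") {
      apply_censoring(values,
                      lower = if (l$type == "threshold") l$value,
                      upper = if (r$type == "threshold") r$value)
    } else {
      apply_censoring(values,
                      p_left = scheme_fraction(scheme, v, "left"),
                      p_right = scheme_fraction(scheme, v, "right"),
                      mode = mode, mu = mu, sigma = sigma)
    }
  }
  cx <- one("x", x, model$mu_x, model$sigma_x)
  cy <- one("y", y, model$mu_y, model$sigma_y)
  censored_sample(cx$values, cy$values, cx$status, cy$status,
                  cx$limits, cy$limits)
}

#' Naive Pearson correlation of censored data
#'
#' The correlation a researcher who ignores censoring would compute:
#' plain Pearson r on the censored values.  Its population value is the
#' attenuated correlation of [attenuated_correlation()].
#'
#' @param sample A [censored_sample()].
#' @return The sample correlation.
#' @export
censored_pearson <- function(sample) {
  stopifnot(inherits(sample, "censored_sample"))
  if (sample$n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(sample$x) == 0 || stats::var(sample$y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  stats::cor(sample$x, sample$y)
}

#' Monte-Carlo estimate of the attenuated correlation
#'
#' Simulates a large standard bivariate normal sample with latent
#' correlation `rho`, censors it according to the scheme, and returns
#' the Pearson correlation of the censored data -- a Monte-Carlo
#' estimate of the population attenuated correlation, with standard
#' error (1 - r^2) / sqrt(n).
#'
#' @param rho Latent correlation.
#' @param scheme A [censoring_scheme()].
#' @param n Simulated sample size (default 500,000).
#' @param seed Integer seed.
#' @param mode Censoring mode, see [censor_sample()].
#' @return An `"attenuation_result"` (see [attenuated_correlation()])
#'   with `method = "monte_carlo"` and `mc_standard_error` set.
#' @examples
#' s <- censoring_scheme(left_x = 0.5, left_y = 0.5)
#' censorcorr(-1, s, n = 1e5, seed = 7)$rho_censored   # near -0.467
#' @export
censorcorr <- function(rho, scheme, n = 500000L, seed = 1L,
                       mode = c("sample", "population")) {
  mode <- match.arg(mode)
  stopifnot(abs(rho) <= 1)
  latent <- sample_latent(bvn_model(rho = rho), n, seed = seed)
  cs <- censor_sample(latent$x, latent$y, scheme, mode = mode)
  r <- censored_pearson(cs)
  structure(
    list(rho_latent = rho, rho_censored = r, scheme = scheme,
         method = "monte_carlo",
         mc_standard_error = (1 - r^2) / sqrt(cs$n)),
    class = "attenuation_result"
  )
}
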