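#' Censoring scheme for a bivariate pair
#'
#' Describes how each member of the pair is censored: on each side
#' (left = floor / limit of detection from below, right = ceiling) a
#' variable is either uncensored, censored by a *fraction* of the
#' distribution, or censored at a *fixed threshold* on the data scale.
#' Fractions refer to the share of the population (or sample, see
#' [apply_censoring()]) pushed to the limit of detection.
#'
#' @param left_x,right_x,left_y,right_y Censoring fractions in \[0, 1).
#'   For each variable `left + right` must be < 1.
#' @param lower_x,upper_x,lower_y,upper_y Optional fixed detection
#'   limits on the data scale; a non-`NULL` threshold overrides the
#'   corresponding fraction.
#'
#' @return An object of class `"censoring_scheme"`: per variable a list
#'   of `left` / `right` side specifications `list(type, value)` with
#'   `type` one of `"none"`, `"fraction"`, `"threshold"`.
#'
#' @examples
#' censoring_scheme(left_x = 0.5, left_y = 0.5)      # 50% floor on both
#' censoring_scheme(left_x = 0.5, right_y = 0.5)     # floor on x, ceiling on y
#' censoring_scheme(lower_x = 0.001)                 # fixed limit of detection
#' @export
censoring_scheme <- function(left_x = 0, right_x = 0, left_y = 0, right_y = 0,
                             lower_x = NULL, upper_x = NULL,
                             lower_y = NULL, upper_y = NULL) {
  side <- function(frac, thr, what) {
    if (!is.null(thr)) {
      stopifnot(is.numeric(thr), length(thr) == 1L, is.finite(thr))
      return(list(type = "threshold", value = as.numeric(thr)))
    }
    stopifnot(is.numeric(frac), length(frac) == 1L, is.finite(frac))
    if (frac < 0 || frac >= 1) {
      stop(sprintf("censoring fraction %s must be in [0, 1)", what),
           call. = FALSE)
    }
    if (frac == 0) list(type = "none", value = NA_real_)
    else list(type = "fraction", value = as.numeric(frac))
  }
  sch <- structure(
    list(
      x = list(left = side(left_x, lower_x, "left_x"),
               right = side(right_x, upper_x, "right_x")),
      y = list(left = side(left_y, lower_y, "left_y"),
               right = side(right_y, upper_y, "right_y"))
    ),
    class = "censoring_scheme"
  )
  for (v in c("x", "y")) {
    l <- sch[[v]]$left; r <- sch[[v]]$right
    if (l$type == "fraction" && r$type == "fraction" &&
        l$value + r$value >= 1) {
      stop(sprintf("variable %s fully censored (left + right >= 1)", v),
           call. = FALSE)
    }
    if (l$type == "threshold" && r$type == "threshold" &&
        l$value >= r$value) {
      stop(sprintf("lower limit must be below upper limit for %s", v),
           call. = FALSE)
    }
  }
  sch
}

#' @export
print.censoring_scheme <- function(x, ...) {
  fmt <- function(s, side) {
    switch(s$type,
           none = "none",
           fraction = sprintf("%g%% %s", 100 * s$value, side),
           threshold = sprintf("%s at %g", side, s$value))
  }
  cat("Censoring scheme\n")
  for (v in c("x", "y")) {
    cat(sprintf("  %s: left %s | right %s\n", v,
                fmt(x[[v]]$left, "left"), fmt(x[[v]]$right, "right")))
  }
  invisible(x)
}

#' Effective detection limits of a scheme
#'
#' Resolves fraction-based sides to quantiles of the latent marginal
#' (population limits) and returns the lower/upper limits per variable,
#' `-Inf`/`Inf` on uncensored sides.
#'
#' @param scheme A [censoring_scheme()].
#' @param model A [bvn_model()] supplying the marginals (default standard).
#' @return A list with numeric `x` and `y`, each `c(lower, upper)`.
#' @export
scheme_limits <- function(scheme, model = bvn_model()) {
  one <- function(v, mu, sigma) {
    l <- scheme[[v]]$left; r <- scheme[[v]]$right
    lo <- switch(l$type,
                 none = -Inf,
                 fraction = stats::qnorm(l$value, mu, sigma),
                 threshold = l$value)
    hi <- switch(r$type,
                 none = Inf,
                 fraction = stats::qnorm(1 - r$value, mu, sigma),
                 threshold = r$value)
    if (lo >= hi) stop("variable fully censored", call. = FALSE)
    c(lower = lo, upper = hi)
  }
  list(x = one("x", model$mu_x, model$sigma_x),
       y = one("y", model$mu_y, model$sigma_y))
}

#' Mirror a censoring scheme
#'
#' Left and right censoring are mirror images: a scheme applied to
#' negated data corresponds to the original data with left and right
#' sides swapped and thresholds negated.  Mirroring both variables
#' leaves the attenuated correlation unchanged; mirroring one variable
#' flips its sign.
#'
#' @param scheme A [censoring_scheme()].
#' @param variables Which variables to mirror (default both).
#' @return The mirrored `censoring_scheme`.
#' @export
mirror_scheme <- function(scheme, variables = c("x", "y")) {
  stopifnot(all(variables %in% c("x", "y")))
  out <- scheme
  for (v in variables) {
    l <- scheme[[v]]$left; r <- scheme[[v]]$right
    neg <- function(s) {
      if (s$type == "threshold") s$value <- -s$value
      s
    }
    out[[v]]$left <- neg(r)
    out[[v]]$right <- neg(l)
  }
  out
}

# Censoring fractions of a scheme side, NA for thresholds.
scheme_fraction <- function(scheme, var, side) {
  s <- scheme[[var]][[side]]
  switch(s$type, none = 0, fraction = s$value, threshold = NA_real_)
}
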