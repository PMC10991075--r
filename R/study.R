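#' Specify one simulation-study cell
#'
#' A cell is one combination of latent correlation, censoring pattern
#' and sample size, evaluated over many simulated trials.  The default
#' evaluation grid of the package's study design crosses 8 correlations
#' (+/-.3, +/-.7, +/-.9, +/-1), 5 left-censoring patterns (30/30,
#' 50/50, 70/70, 0/50, 30/70 percent on x/y) and 2 sample sizes
#' (200, 500) -- 80 cells, each run in replicate.
#'
#' @param rho Latent correlation.
#' @param scheme A [censoring_scheme()].
#' @param n Sample size per trial (>= 10).
#' @param trials Trials per replication (>= 1; classic choice 1000).
#' @param replications Number of independent replications (default 2).
#' @param estimators Parameterizations to fit, subset of
#'   `c("unconstrained", "constrained")`.
#' @param ci_methods Interval methods, subset of
#'   `c("wald_unconstrained", "wald_constrained", "profile")`.
#' @param seed Master seed for the cell.
#' @return An object of class `"cell_spec"`.
#' @export
cell_spec <- function(rho, scheme, n, trials = 1000L, replications = 2L,
                      estimators = c("unconstrained", "constrained"),
                      ci_methods = c("wald_unconstrained",
                                     "wald_constrained", "profile"),
                      seed = 1L) {
  stopifnot(abs(rho) <= 1, inherits(scheme, "censoring_scheme"),
            n >= 10, trials >= 1, replications >= 1,
            all(estimators %in% c("unconstrained", "constrained")),
            all(ci_methods %in% c("wald_unconstrained", "wald_constrained",
                                  "profile")))
  structure(
    list(rho = rho, scheme = scheme, n = as.integer(n),
         trials = as.integer(trials), replications = as.integer(replications),
         estimators = estimators, ci_methods = ci_methods,
         seed = as.integer(seed)),
    class = "cell_spec")
}

# deterministic per-trial seed below 2^31, mixing cell/replication/trial
mix_seed <- function(seed, cell, replication, trial) {
  (as.double(seed) * 2654435761 + cell * 40503 +
     replication * 65537 + trial * 2246822519) %% 2147483647
}

#' Run one replication of a simulation-study cell
#'
#' For each trial: draw a latent bivariate normal sample, censor it
#' (sample-percentile rule), fit the requested estimators, and form the
#' requested confidence intervals.  Trials where an estimator or
#' interval fails are excluded from that statistic's aggregation but
#' counted in its convergence proportion.
#'
#' @param spec A [cell_spec()].
#' @param cell_index Integer tag entering the per-trial seeds, so cells
#'   of a grid are reproducible independently.
#' @param replication Which replication to run (enters the seeds).
#' @return A data frame, one row per estimator and per CI method, with
#'   the cell descriptors and the summary statistics: for estimators
#'   `proportion_converged`, `mean_est`, `sd_est`, `min_est`,
#'   `max_est`, `bias`, `rmse`; for intervals `proportion_converged`,
#'   `mean_midpoint`, `coverage`, `max_width`, `mean_width`,
#'   `median_width`, `proportion_width_ge_2`.
#' @export
run_cell <- function(spec, cell_index = 1L, replication = 1L) {
  stopifnot(inherits(spec, "cell_spec"))
  need_unc <- "unconstrained" %in% spec$estimators ||
    "wald_unconstrained" %in% spec$ci_methods
  need_con <- "constrained" %in% spec$estimators ||
    any(c("wald_constrained", "profile") %in% spec$ci_methods)

  est <- list(unconstrained = numeric(0), constrained = numeric(0))
  est_ok <- list(unconstrained = logical(0), constrained = logical(0))
  ci_rows <- list()
  for (m in spec$ci_methods) {
    ci_rows[[m]] <- data.frame(converged = logical(0), lower = numeric(0),
                               upper = numeric(0))
  }
  model <- bvn_model(rho = spec$rho)

  for (t in seq_len(spec$trials)) {
    seed_t <- mix_seed(spec$seed, cell_index, replication, t)
    latent <- sample_latent(model, spec$n, seed = seed_t)
    cs <- tryCatch(censor_sample(latent$x, latent$y, spec$scheme),
                   error = function(e) NULL)
    fits <- list()
    if (!is.null(cs)) {
      if (need_unc) {
        fits$unconstrained <- tryCatch(
          fit_censored(cs, "unconstrained"), error = function(e) NULL)
      }
      if (need_con) {
        fits$constrained <- tryCatch(
          fit_censored(cs, "constrained"), error = function(e) NULL)
      }
    }
    for (p in spec$estimators) {
      f <- fits[[p]]
      ok <- !is.null(f) && f$converged
      est_ok[[p]] <- c(est_ok[[p]], ok)
      est[[p]] <- c(est[[p]], if (ok) f$model_hat$rho else NA_real_)
    }
    for (m in spec$ci_methods) {
      ci <- NULL
      if (m == "wald_unconstrained" && !is.null(fits$unconstrained)) {
        ci <- wald_ci(fits$unconstrained, cs)
      } else if (m == "wald_constrained" && !is.null(fits$constrained)) {
        ci <- wald_ci(fits$constrained, cs)
      } else if (m == "profile" && !is.null(fits$constrained)) {
        ci <- profile_ci(fits$constrained, cs)
      }
      ok <- !is.null(ci) && isTRUE(ci$converged)
      ci_rows[[m]] <- rbind(ci_rows[[m]], data.frame(
        converged = ok,
        lower = if (ok) ci$lower else NA_real_,
        upper = if (ok) ci$upper else NA_real_))
    }
  }

  base <- data.frame(
    rho = spec$rho, n = spec$n, trials = spec$trials,
    replication = replication, pattern = pattern_label(spec$scheme),
    stringsAsFactors = FALSE)
  rows <- list()
  for (p in spec$estimators) {
    e <- est[[p]][est_ok[[p]]]
    rows[[length(rows) + 1L]] <- cbind(base, data.frame(
      kind = "estimate", method = p,
      proportion_converged = mean(est_ok[[p]]),
      mean_est = mean_or_na(e), sd_est = sd_or_na(e),
      min_est = min_or_na(e), max_est = max_or_na(e),
      bias = mean_or_na(e) - spec$rho,
      rmse = if (length(e)) sqrt(mean((e - spec$rho)^2)) else NA_real_,
      mean_midpoint = NA_real_, coverage = NA_real_,
      max_width = NA_real_, mean_width = NA_real_,
      median_width = NA_real_, proportion_width_ge_2 = NA_real_,
      stringsAsFactors = FALSE))
  }
  for (m in spec$ci_methods) {
    d <- ci_rows[[m]]
    ok <- d$converged
    lw <- d$lower[ok]; up <- d$upper[ok]
    w <- up - lw
    cover <- lw <= spec$rho & spec$rho <= up
    rows[[length(rows) + 1L]] <- cbind(base, data.frame(
      kind = "interval", method = m,
      proportion_converged = mean(ok),
      mean_est = NA_real_, sd_est = NA_real_, min_est = NA_real_,
      max_est = NA_real_, bias = NA_real_, rmse = NA_real_,
      mean_midpoint = mean_or_na((lw + up) / 2),
      coverage = mean_or_na(cover),
      max_width = max_or_na(w), mean_width = mean_or_na(w),
      median_width = if (length(w)) stats::median(w) else NA_real_,
      proportion_width_ge_2 = mean_or_na(w >= 2),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
min_or_na <- function(x) if (length(x)) min(x) else NA_real_
max_or_na <- function(x) if (length(x)) max(x) else NA_real_

pattern_label <- function(scheme) {
  lab <- function(v) {
    l <- scheme[[v]]$left; r <- scheme[[v]]$right
    sprintf("%s/%s",
            if (l$type == "fraction") sprintf("%gL", 100 * l$value)
            else if (l$type == "threshold") "thrL" else "0",
            if (r$type == "fraction") sprintf("%gR", 100 * r$value)
            else if (r$type == "threshold") "thrR" else "0")
  }
  paste(lab("x"), lab("y"), sep = " | ")
}

#' Run a full simulation study
#'
#' Iterates the cells of a study configuration (grid of correlations x
#' censoring patterns x sample sizes, each with the configured number
#' of replications) and binds the per-cell summaries into one table.
#' Cells are seeded independently, so the result does not depend on
#' execution order; failed cells are recorded with `NA` statistics and
#' the run continues.
#'
#' @param config A list (or path to a YAML file, see
#'   [read_study_config()]) with elements `rho_values`, `patterns`
#'   (list of lists with fractions `left_x`, `right_x`, `left_y`,
#'   `right_y`), `sample_sizes`, `trials`, `replications`,
#'   `estimators`, `ci_methods`, `seed`, and optionally `out` (CSV
#'   path).
#' @return A data frame, one row per cell x replication x
#'   estimator/CI method (invisibly written to `config$out` if set).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  defaults <- list(trials = 1000L, replications = 2L,
                   estimators = c("unconstrained", "constrained"),
                   ci_methods = c("wald_unconstrained", "wald_constrained",
                                  "profile"),
                   seed = 1L, out = NULL)
  config <- utils::modifyList(defaults, config)
  stopifnot(!is.null(config$rho_values), !is.null(config$patterns),
            !is.null(config$sample_sizes))

  grid <- expand.grid(pi_ = seq_along(config$patterns),
                      n_ = seq_along(config$sample_sizes),
                      ri_ = seq_along(config$rho_values))
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    pat <- config$patterns[[grid$pi_[ci]]]
    scheme <- censoring_scheme(
      left_x = pat$left_x %||% 0, right_x = pat$right_x %||% 0,
      left_y = pat$left_y %||% 0, right_y = pat$right_y %||% 0)
    spec <- cell_spec(
      rho = config$rho_values[grid$ri_[ci]], scheme = scheme,
      n = config$sample_sizes[grid$n_[ci]],
      trials = config$trials, replications = config$replications,
      estimators = config$estimators, ci_methods = config$ci_methods,
      seed = config$seed)
    for (rep_i in seq_len(spec$replications)) {
      res <- tryCatch(run_cell(spec, cell_index = ci, replication = rep_i),
                      error = function(e) {
                        warning(sprintf("cell %d replication %d failed: %s",
                                        ci, rep_i, conditionMessage(e)),
                                call. = FALSE)
                        NULL
                      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$out)) {
    utils::write.csv(out, config$out, row.names = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study configuration from YAML
#'
#' @param path Path to a YAML file with the keys described in
#'   [run_study()].
#' @return The configuration list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$rho_values)) cfg$rho_values <- as.numeric(cfg$rho_values)
  if (!is.null(cfg$sample_sizes)) {
    cfg$sample_sizes <- as.integer(cfg$sample_sizes)
  }
  cfg
}

#' Pool replications of a study table
#'
#' Averages every summary statistic over the replications of each
#' cell x method combination (proportions and means pool exactly when
#' replications share the trial count; extrema use min/max).
#'
#' @param study A table from [run_study()].
#' @return One row per cell x method.
#' @export
pool_replications <- function(study) {
  key <- interaction(study$rho, study$n, study$pattern, study$kind,
                     study$method, drop = TRUE)
  parts <- split(study, key)
  out <- lapply(parts, function(d) {
    pooled <- d[1L, , drop = FALSE]
    pooled$replication <- NA_integer_
    pooled$trials <- sum(d$trials)
    for (col in c("proportion_converged", "mean_est", "sd_est", "bias",
                  "rmse", "mean_midpoint", "coverage", "mean_width",
                  "median_width", "proportion_width_ge_2")) {
      pooled[[col]] <- mean_or_na(d[[col]][!is.na(d[[col]])])
    }
    pooled$min_est <- min_or_na(d$min_est[!is.na(d$min_est)])
    pooled$max_est <- max_or_na(d$max_est[!is.na(d$max_est)])
    pooled$max_width <- max_or_na(d$max_width[!is.na(d$max_width)])
    pooled
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference RMSE of the uncensored Pearson correlation
#'
#' Large-sample reference for comparison with censored-data estimators:
#' sqrt(SE^2 + bias^2) with SE = sqrt((1 - rho^2) / (n - 2)) and the
#' classical small-sample bias approximation -rho (1 - rho^2) / (2n).
#'
#' @param rho True correlation.
#' @param n Sample size (> 2).
#' @return The reference RMSE.
#' @examples
#' round(reference_uncensored_rmse(0.3, 200), 2)  # 0.07
#' @export
reference_uncensored_rmse <- function(rho, n) {
  stopifnot(abs(rho) <= 1)
  if (n <= 2) stop("n must exceed 2", call. = FALSE)
  se2 <- (1 - rho^2) / (n - 2)
  bias <- -rho * (1 - rho^2) / (2 * n)
  sqrt(se2 + bias^2)
}

#' Reference width of the uncensored correlation confidence interval
#'
#' Width of the Fisher r-to-z interval
#' tanh(atanh(rho) +/- z / sqrt(n - 3)) for the Pearson correlation of
#' uncensored data.
#'
#' @param rho True correlation (|rho| <= 1; exactly +/-1 gives width 0).
#' @param n Sample size (> 3).
#' @param level Confidence level (default 0.95).
#' @return The interval width.
#' @examples
#' round(reference_uncensored_ci_width(0.7, 200), 3)  # 0.143 (printed .142)
#' @export
reference_uncensored_ci_width <- function(rho, n, level = 0.95) {
  stopifnot(abs(rho) <= 1, level > 0, level < 1)
  if (abs(rho) == 1) return(0)
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  d <- stats::qnorm((1 + level) / 2) / sqrt(n - 3)
  tanh(atanh(rho) + d) - tanh(atanh(rho) - d)
}
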