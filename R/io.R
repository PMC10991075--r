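#' Write a censored sample to CSV
#'
#' Statuses are stored alongside the values (`obs`, `left`, `right`),
#' so detection limits are never inferred from magic numbers.
#'
#' @param sample A [censored_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_censored_csv <- function(sample, path) {
  stopifnot(inherits(sample, "censored_sample"))
  # %.17g round-trips doubles exactly
  utils::write.csv(
    data.frame(x = sprintf("%.17g", sample$x),
               y = sprintf("%.17g", sample$y),
               x_status = sample$x_status, y_status = sample$y_status),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a censored sample from CSV
#'
#' Two ways to mark censoring: explicit status columns with tokens
#' `obs` / `left` / `right`, or global detection limits, in which case
#' every value at or beyond a limit is converted to the corresponding
#' status and set to the limit.
#'
#' @param path CSV path (comma-delimited, header required).
#' @param x,y Names of the value columns.
#' @param x_status,y_status Names of the status columns (`NULL` to use
#'   detection limits instead).
#' @param lower_x,upper_x,lower_y,upper_y Optional global detection
#'   limits, used when status columns are absent.
#' @return A [censored_sample()].
#' @export
read_censored_csv <- function(path, x = "x", y = "y",
                              x_status = "x_status", y_status = "y_status",
                              lower_x = NULL, upper_x = NULL,
                              lower_y = NULL, upper_y = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(x, y)) {
    if (!col %in% names(d)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
    if (!is.numeric(d[[col]])) {
      stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
    }
  }
  one <- function(vals, status_col, lower, upper, name) {
    if (!is.null(status_col) && status_col %in% names(d)) {
      st <- d[[status_col]]
      bad <- which(!st %in% c("obs", "left", "right"))
      if (length(bad)) {
        stop(sprintf("invalid status token '%s' at row %d, column %s",
                     st[bad[1L]], bad[1L], status_col), call. = FALSE)
      }
      lims <- c(if (any(st == "left")) vals[st == "left"][1L] else -Inf,
                if (any(st == "right")) vals[st == "right"][1L] else Inf)
      list(values = vals, status = st, limits = lims)
    } else {
      apply_censoring(vals, lower = lower, upper = upper)
    }
  }
  has_status <- function(col) !is.null(col) && col %in% names(d)
  if (!has_status(x_status) && is.null(lower_x) && is.null(upper_x) &&
      !has_status(y_status) && is.null(lower_y) && is.null(upper_y)) {
    # fully observed data
    return(censored_sample(d[[x]], d[[y]]))
  }
  cx <- one(d[[x]], if (has_status(x_status)) x_status, lower_x, upper_x, "x")
  cy <- one(d[[y]], if (has_status(y_status)) y_status, lower_y, upper_y, "y")
  censored_sample(cx$values, cy$values, cx$status, cy$status,
                  cx$limits, cy$limits)
}
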