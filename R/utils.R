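# Internal helpers shared across modules.

# Input-validation failure with a stable condition class so callers and tests
# can distinguish bad input from numerical failure.
stop_input <- function(msg, class = "ocukin_input_error") {
  abort(msg, class = c(class, "ocukin_error"))
}

check_numeric <- function(x, name, min = -Inf, strict_min = FALSE,
                          finite = TRUE, len = NULL) {
  if (!is.numeric(x)) stop_input(sprintf("`%s` must be numeric", name))
  if (!is.null(len) && length(x) != len) {
    stop_input(sprintf("`%s` must have length %d", name, len))
  }
  if (finite && any(!is.finite(x))) {
    stop_input(sprintf("`%s` must be finite", name))
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad) {
    op <- if (strict_min) ">" else ">="
    stop_input(sprintf("`%s` must be %s %g", name, op, min))
  }
  invisible(x)
}

check_times <- function(times, name = "times", strictly_increasing = TRUE) {
  check_numeric(times, name, min = 0)
  if (strictly_increasing && any(diff(times) <= 0)) {
    stop_input(sprintf("`%s` must be strictly increasing", name))
  }
  invisible(times)
}

check_same_length <- function(...) {
  args <- list(...)
  lens <- vapply(args, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop_input(sprintf(
      "length mismatch: %s",
      paste(sprintf("%s (%d)", names(args), lens), collapse = ", ")
    ))
  }
  invisible(lens[[1]])
}

# Ordinary least squares of y on x with the diagnostics the fitting modules
# need. R-squared conventions: centered for models with an intercept,
# uncentered for through-origin fits (both bounded in [0, 1]); an exact fit of
# a constant response is reported as R^2 = 1 rather than NaN.
ols_line <- function(x, y, intercept = TRUE) {
  n <- length(x)
  if (intercept) {
    xb <- mean(x)
    yb <- mean(y)
    sxx <- sum((x - xb)^2)
    if (sxx == 0) stop_input("degenerate regressor: all x values equal")
    slope <- sum((x - xb) * (y - yb)) / sxx
    b0 <- yb - slope * xb
  } else {
    sxx <- sum(x^2)
    if (sxx == 0) stop_input("degenerate regressor: all x values zero")
    slope <- sum(x * y) / sxx
    b0 <- 0
  }
  ss_res <- sum((y - b0 - slope * x)^2)
  ss_tot <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (ss_tot <= .Machine$double.eps^0.5 * max(1, sum(y^2))) {
    if (ss_res <= ss_tot) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  p <- if (intercept) 2L else 1L
  adj_r2 <- if (n > p) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  list(slope = slope, intercept = b0, r_squared = r2,
       adj_r_squared = adj_r2, n = n)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
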