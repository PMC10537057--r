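# In vitro release kinetics: cumulative percent drug released from
# dialysis-bag sampling records, and the Higuchi square-root-of-time model.

#' Construct a dialysis-bag release experiment
#'
#' Holds the sampling record of an in vitro release experiment: supernatant
#' drug concentrations measured at each withdrawal, assay dilution factors,
#' the aliquot and medium volumes, and the dose loaded into the bag.
#'
#' @param times Sampling times (h), strictly increasing, nonnegative.
#' @param concentrations Measured supernatant concentration per sample (µg/mL).
#' @param dilution_factors Per-sample assay dilution (dimensionless); recycled
#'   from length 1.
#' @param sample_volume Aliquot volume withdrawn and replaced per sample (mL).
#' @param medium_volume Release-medium volume (mL); 50 mL of simulated tear
#'   fluid in the standard corneal release setup.
#' @param dose Initial drug amount in the bag (µg), > 0.
#' @return An object of class `release_experiment`.
#' @examples
#' release_experiment(times = c(1, 2), concentrations = c(5, 8),
#'                    sample_volume = 1, medium_volume = 50, dose = 1000)
#' @export
release_experiment <- function(times, concentrations, dilution_factors = 1,
                               sample_volume = 0, medium_volume = 50, dose) {
  check_times(times)
  check_numeric(concentrations, "concentrations", min = 0)
  if (length(dilution_factors) == 1) {
    dilution_factors <- rep(dilution_factors, length(times))
  }
  check_numeric(dilution_factors, "dilution_factors", min = 0, strict_min = TRUE)
  check_same_length(times = times, concentrations = concentrations,
                    dilution_factors = dilution_factors)
  check_numeric(sample_volume, "sample_volume", min = 0, len = 1)
  check_numeric(medium_volume, "medium_volume", min = 0, strict_min = TRUE, len = 1)
  if (missing(dose)) stop_input("`dose` is required")
  check_numeric(dose, "dose", len = 1)
  if (dose <= 0) stop_input("`dose` must be > 0")
  structure(
    list(times = times, concentrations = concentrations,
         dilution_factors = dilution_factors, sample_volume = sample_volume,
         medium_volume = medium_volume, dose = dose),
    class = "release_experiment"
  )
}

#' @export
print.release_experiment <- function(x, ...) {
  cat(sprintf(
    "<release_experiment> %d samples over %g-%g h; dose %g ug in %g mL medium (aliquot %g mL)\n",
    length(x$times), min(x$times), max(x$times), x$dose, x$medium_volume,
    x$sample_volume
  ))
  invisible(x)
}

new_release_curve <- function(times, percent, estimator) {
  if (any(percent > 100)) {
    warn(sprintf(
      "%d release value(s) exceed 100%% of the dose (max %.2f%%); retained unclipped",
      sum(percent > 100), max(percent)
    ), class = "ocukin_over_release")
  }
  structure(
    tibble::tibble(times = times, percent_released = percent),
    estimator = estimator,
    class = c("release_curve", class(tibble::tibble()))
  )
}

#' Cumulative percent released, uncorrected estimator
#'
#' The textbook dissolution estimator: at each time point,
#' `%DR = Conc x dilution_factor x medium_volume / dose x 100`. It ignores the
#' drug mass carried out in earlier aliquots, so under a withdraw-and-replace
#' sampling protocol it underestimates late cumulative release; see
#' [percent_released_corrected()] for the mass-conserving version.
#'
#' @param exp A [release_experiment()].
#' @return A `release_curve` tibble (`times`, `percent_released`) with
#'   attribute `estimator = "verbatim_eq1"`. Values above 100 percent raise a
#'   warning but are retained (assay noise can exceed the dose).
#' @examples
#' exp <- release_experiment(times = c(1, 2), concentrations = c(10, 12),
#'                           sample_volume = 1, medium_volume = 50, dose = 1000)
#' percent_released_eq1(exp)
#' @export
percent_released_eq1 <- function(exp) {
  stopifnot(inherits(exp, "release_experiment"))
  pct <- exp$concentrations * exp$dilution_factors * exp$medium_volume /
    exp$dose * 100
  new_release_curve(exp$times, pct, "verbatim_eq1")
}

#' Cumulative percent released, withdrawal-corrected estimator
#'
#' Mass-conserving estimator for withdraw-and-replace sampling: the cumulative
#' released amount at sample `n` is the drug currently in the medium plus all
#' drug carried out in earlier aliquots,
#' `C_n * DF_n * V_medium + sum_{i<n} C_i * DF_i * V_sample`. With
#' `sample_volume = 0` it reduces exactly to [percent_released_eq1()].
#'
#' @inheritParams percent_released_eq1
#' @return A `release_curve` with attribute `estimator = "withdrawal_corrected"`.
#' @examples
#' exp <- release_experiment(times = c(1, 2), concentrations = c(10, 10),
#'                           sample_volume = 1, medium_volume = 50, dose = 1000)
#' percent_released_corrected(exp)  # 50%, 51%
#' @export
percent_released_corrected <- function(exp) {
  stopifnot(inherits(exp, "release_experiment"))
  mass_sampled <- exp$concentrations * exp$dilution_factors * exp$sample_volume
  removed_before <- c(0, cumsum(mass_sampled)[-length(mass_sampled)])
  amount <- exp$concentrations * exp$dilution_factors * exp$medium_volume +
    removed_before
  new_release_curve(exp$times, amount / exp$dose * 100, "withdrawal_corrected")
}

#' Fit the Higuchi square-root-of-time release model
#'
#' Ordinary least squares of cumulative percent released against the square
#' root of time. Under matrix-diffusion-controlled release the plot is linear
#' with slope `k_H` (percent per square-root hour).
#'
#' @param curve A `release_curve`, or any data frame with columns `times` and
#'   `percent_released`.
#' @param fit_intercept Fit a free intercept (default) or force the line
#'   through the origin. The slope is reported either way; with
#'   `fit_intercept = FALSE` the intercept is 0 and R-squared is the
#'   uncentered coefficient of determination.
#' @return An object of class `higuchi_fit`: `k_h`, `intercept`, `r_squared`,
#'   `n`.
#' @examples
#' curve <- tibble::tibble(times = c(1, 4, 9), percent_released = 25 * sqrt(c(1, 4, 9)))
#' fit_higuchi(curve)
#' @export
fit_higuchi <- function(curve, fit_intercept = TRUE) {
  if (!is.data.frame(curve) ||
      !all(c("times", "percent_released") %in% names(curve))) {
    stop_input("`curve` must have columns `times` and `percent_released`")
  }
  keep <- curve$times > 0
  if (sum(keep) < 3) {
    abort("Higuchi fit needs at least 3 points with t > 0",
          class = c("ocukin_insufficient_data", "ocukin_error"))
  }
  fit <- ols_line(sqrt(curve$times[keep]), curve$percent_released[keep],
                  intercept = fit_intercept)
  structure(
    list(k_h = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, n = fit$n),
    class = "higuchi_fit"
  )
}

#' @export
print.higuchi_fit <- function(x, ...) {
  cat(sprintf(
    "<higuchi_fit> k_H = %s %%/sqrt(h), intercept = %s %%, R^2 = %s (n = %d)\n",
    fmt_num(x$k_h), fmt_num(x$intercept), fmt_num(x$r_squared, 6), x$n
  ))
  invisible(x)
}
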