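# Ex vivo transcorneal permeation: steady-state flux, apparent permeability,
# lag time and enhancement ratio from cumulative-permeation curves.

#' Construct a transcorneal permeation experiment
#'
#' Cumulative permeated drug amount per unit corneal area over time from a
#' Franz-type diffusion cell, together with the donor concentration and the
#' exposed corneal cross-section. Defaults match the standard rabbit-cornea
#' setup (0.636 cm² cross-section, 500 µg/mL donor).
#'
#' @param times Sampling times (h), strictly increasing.
#' @param q_cumulative Cumulative permeated amount per area (µg/cm²), >= 0.
#' @param c0 Donor compartment concentration (µg/mL), > 0.
#' @param area Exposed corneal area (cm²), > 0.
#' @param label Formulation name.
#' @return An object of class `permeation_experiment`.
#' @export
permeation_experiment <- function(times, q_cumulative, c0 = 500, area = 0.636,
                                  label = "") {
  check_times(times)
  check_numeric(q_cumulative, "q_cumulative", min = 0)
  check_same_length(times = times, q_cumulative = q_cumulative)
  check_numeric(c0, "c0", min = 0, strict_min = TRUE, len = 1)
  check_numeric(area, "area", min = 0, strict_min = TRUE, len = 1)
  structure(
    list(times = times, q_cumulative = q_cumulative, c0 = c0, area = area,
         label = as.character(label)),
    class = "permeation_experiment"
  )
}

#' @export
print.permeation_experiment <- function(x, ...) {
  cat(sprintf(
    "<permeation_experiment> %s: %d samples over %g-%g h; C0 = %g ug/mL, area = %g cm^2\n",
    if (nzchar(x$label)) x$label else "(unlabelled)", length(x$times),
    min(x$times), max(x$times), x$c0, x$area
  ))
  invisible(x)
}

#' Steady-state flux and apparent permeability
#'
#' Fits the steady-state portion of a cumulative-permeation curve by ordinary
#' least squares of `Q` on `t`. The flux is the slope `J = dQ/dt`
#' (µg cm^-2 h^-1), the apparent permeability is `Papp = J / C0` (cm/h), and
#' the lag time is the positive-slope x-intercept `-intercept/J`.
#'
#' If no `window` is given the steady-state window is chosen automatically as
#' the contiguous tail window of at least 4 points maximising R-squared (ties
#' broken toward the longer window), the usual late-linear reading of a
#' lag-then-linear permeation curve. Curves with fewer than 4 points are fit
#' whole.
#'
#' @param exp A [permeation_experiment()].
#' @param window Optional numeric `c(t_min, t_max)` restricting the regression
#'   to samples with `t_min <= t <= t_max`.
#' @return An object of class `permeation_result`: `flux_j`, `p_app`, `t_lag`
#'   (NA when the slope is not positive), `window` (integer indices used),
#'   `r_squared`, `label`. A negative fitted slope raises a warning but the
#'   result is retained.
#' @examples
#' exp <- permeation_experiment(1:6, 5 * (1:6) - 2, c0 = 500)
#' steady_state_flux(exp)  # J = 5, t_lag = 0.4
#' @export
steady_state_flux <- function(exp, window = NULL) {
  stopifnot(inherits(exp, "permeation_experiment"))
  n <- length(exp$times)
  if (!is.null(window)) {
    check_numeric(window, "window", len = 2)
    idx <- which(exp$times >= window[1] & exp$times <= window[2])
    if (length(idx) < 3) {
      abort("chosen window contains fewer than 3 points",
            class = c("ocukin_insufficient_data", "ocukin_error"))
    }
  } else if (n < 3) {
    abort("steady-state fit needs at least 3 points",
          class = c("ocukin_insufficient_data", "ocukin_error"))
  } else if (n < 4) {
    idx <- seq_len(n)
  } else {
    # candidate windows: last k points, k = 4..n; best R^2, ties -> longer
    cands <- lapply(seq(4, n), function(k) {
      cand <- seq(n - k + 1, n)
      list(idx = cand, r2 = ols_line(exp$times[cand], exp$q_cumulative[cand])$r_squared)
    })
    top <- max(vapply(cands, function(c) c$r2, numeric(1)))
    idx <- NULL
    for (c in cands) if (c$r2 >= top - 1e-9) idx <- c$idx  # ordered by k: longest wins
  }
  t_w <- exp$times[idx]
  if (length(unique(t_w)) < 2) {
    abort("all sampling times in the window are equal; flux fit is singular",
          class = c("ocukin_singular_fit", "ocukin_error"))
  }
  fit <- ols_line(t_w, exp$q_cumulative[idx])
  if (fit$slope < 0) {
    warn(sprintf("fitted flux is negative (%s ug/cm^2/h); check the curve",
                 fmt_num(fit$slope)), class = "ocukin_negative_flux")
  }
  t_lag <- if (fit$slope > 0) -fit$intercept / fit$slope else NA_real_
  structure(
    list(flux_j = fit$slope, p_app = fit$slope / exp$c0, t_lag = t_lag,
         window = idx, r_squared = fit$r_squared, c0 = exp$c0,
         label = exp$label),
    class = "permeation_result"
  )
}

#' @export
print.permeation_result <- function(x, ...) {
  cat(sprintf(
    "<permeation_result> %s: J = %s ug/cm^2/h, Papp = %s cm/h, t_lag = %s h, R^2 = %s (%d pts)\n",
    if (nzchar(x$label)) x$label else "(unlabelled)", fmt_num(x$flux_j),
    fmt_num(x$p_app), fmt_num(x$t_lag), fmt_num(x$r_squared, 6),
    length(x$window)
  ))
  invisible(x)
}

#' Flux enhancement ratio of a test formulation over a reference
#'
#' Ratio of steady-state fluxes, `J_test / J_reference`. Inputs may be
#' [steady_state_flux()] results or bare flux values; vectors of
#' per-replicate fluxes are averaged after division when
#' `per_replicate = TRUE` (the convention behind reported ratio +/- SD), and
#' divided as mean fluxes otherwise.
#'
#' @param test,reference `permeation_result` objects or numeric fluxes.
#' @param per_replicate Average per-replicate ratios instead of dividing mean
#'   fluxes (vector inputs only).
#' @return The dimensionless enhancement ratio (scalar).
#' @examples
#' enhancement_ratio(8.27, 1.76)  # 4.70
#' @export
enhancement_ratio <- function(test, reference, per_replicate = FALSE) {
  as_flux <- function(x) if (inherits(x, "permeation_result")) x$flux_j else x
  jt <- as_flux(test)
  jr <- as_flux(reference)
  check_numeric(jt, "test")
  check_numeric(jr, "reference")
  if (any(jr <= 0)) {
    abort("reference flux must be > 0 for an enhancement ratio",
          class = c("ocukin_undefined_ratio", "ocukin_error"))
  }
  if (per_replicate) {
    check_same_length(test = jt, reference = jr)
    mean(jt / jr)
  } else {
    mean(jt) / mean(jr)
  }
}

#' Cumulative permeated amount from receptor-compartment concentrations
#'
#' Converts sampled receptor concentrations to the cumulative permeated
#' amount per unit corneal area, correcting for the drug withdrawn in earlier
#' aliquots exactly as in [percent_released_corrected()]:
#' `Q_n = (C_n * V_receptor + sum_{i<n} C_i * V_sample) / area`.
#'
#' @param times Sampling times (h).
#' @param receptor_conc Receptor concentration per sample (µg/mL).
#' @param receptor_volume Receptor compartment volume (mL); 6.9 mL in the
#'   standard corneal Franz cell.
#' @param sample_volume Aliquot withdrawn and replaced per sample (mL).
#' @param area Exposed corneal area (cm²).
#' @param c0,label Passed to the returned [permeation_experiment()].
#' @return A [permeation_experiment()].
#' @examples
#' cumulative_from_receptor_conc(c(1, 2), c(1, 1), receptor_volume = 6.9,
#'                               sample_volume = 0, area = 0.636)
#' @export
cumulative_from_receptor_conc <- function(times, receptor_conc,
                                          receptor_volume = 6.9,
                                          sample_volume = 0, area = 0.636,
                                          c0 = 500, label = "") {
  check_times(times)
  check_numeric(receptor_conc, "receptor_conc", min = 0)
  check_same_length(times = times, receptor_conc = receptor_conc)
  check_numeric(receptor_volume, "receptor_volume", min = 0, strict_min = TRUE, len = 1)
  check_numeric(sample_volume, "sample_volume", min = 0, len = 1)
  check_numeric(area, "area", min = 0, strict_min = TRUE, len = 1)
  removed_before <- c(0, cumsum(receptor_conc * sample_volume)[-length(times)])
  q <- (receptor_conc * receptor_volume + removed_before) / area
  permeation_experiment(times, q, c0 = c0, area = area, label = label)
}

#' Convert a permeation rate between per-second and per-hour units
#'
#' Flux and permeability are often written per second but reported per hour;
#' this converts scalars or vectors between the two.
#'
#' @param x Rate value(s).
#' @param from,to `"per_s"` or `"per_h"`.
#' @return `x` expressed in the `to` unit.
#' @examples
#' convert_rate(17.81 / 3600, from = "per_s", to = "per_h")
#' @export
convert_rate <- function(x, from = c("per_h", "per_s"), to = c("per_h", "per_s")) {
  from <- match.arg(from)
  to <- match.arg(to)
  factor <- c(per_s = 3600, per_h = 1)  # hours per unit time
  x * factor[[from]] / factor[[to]]
}
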