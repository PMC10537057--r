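# Non-compartmental pharmacokinetic analysis of aqueous-humor
# concentration-time profiles: Cmax/Tmax, trapezoidal AUC and AUMC, terminal
# slope, extrapolation to infinity, MRT, and fold-change comparisons.

#' Construct a concentration-time profile
#'
#' One subject's (or one group mean) drug concentrations in aqueous humor
#' over time.
#'
#' @param times Sampling times (h), strictly increasing, nonnegative.
#' @param concentrations Concentrations (ng/mL), >= 0.
#' @param subject_id,formulation Labels.
#' @param loq Optional lower limit of quantification (ng/mL). [run_nca()]
#'   drops values below `loq` after the last quantifiable point and treats
#'   earlier sub-LOQ values as missing.
#' @return An object of class `conc_time_profile`.
#' @examples
#' conc_time_profile(c(0, 1, 2), c(0, 5, 3))
#' @export
conc_time_profile <- function(times, concentrations, subject_id = NA,
                              formulation = NA, loq = NULL) {
  check_times(times)
  check_numeric(concentrations, "concentrations", min = 0)
  check_same_length(times = times, concentrations = concentrations)
  if (!is.null(loq)) check_numeric(loq, "loq", min = 0, len = 1)
  structure(
    list(times = times, concentrations = concentrations,
         subject_id = subject_id, formulation = formulation, loq = loq),
    class = "conc_time_profile"
  )
}

#' @export
print.conc_time_profile <- function(x, ...) {
  cat(sprintf(
    "<conc_time_profile> %s / %s: %d samples, t = %g-%g h, Cmax = %s ng/mL\n",
    x$formulation, x$subject_id, length(x$times), min(x$times), max(x$times),
    fmt_num(max(x$concentrations))
  ))
  invisible(x)
}

#' @export
as.data.frame.conc_time_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, formulation = x$formulation,
             time_h = x$times, conc_ng_per_ml = x$concentrations)
}

#' Maximum observed concentration and its time
#'
#' @param profile A [conc_time_profile()].
#' @return A list with `c_max` (ng/mL) and `t_max` (h); ties in concentration
#'   resolve to the earliest time.
#' @examples
#' cmax_tmax(conc_time_profile(c(0, 1, 2), c(0, 5, 3)))
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "conc_time_profile"))
  if (length(profile$times) < 1) stop_input("profile is empty")
  i <- which.max(profile$concentrations)  # first maximum -> earliest time
  list(c_max = profile$concentrations[i], t_max = profile$times[i])
}

# One trapezoid. Linear everywhere by default; the log-down ("linlog")
# variant uses the log trapezoid on strictly decreasing positive segments.
trapezoid_area <- function(t1, t2, c1, c2, method = "linear") {
  dt <- t2 - t1
  if (method == "linlog" && c2 < c1 && c2 > 0) {
    dt * (c1 - c2) / log(c1 / c2)
  } else {
    dt * (c1 + c2) / 2
  }
}

interp_conc <- function(profile, t) {
  stats::approx(profile$times, profile$concentrations, xout = t)$y
}

#' Trapezoidal area under the concentration-time curve
#'
#' Sum of per-interval trapezoids from `t_start` to `t_end`, with linear
#' interpolation when an endpoint falls between samples. The default rule is
#' linear-linear on every interval; `method = "linlog"` switches declining
#' positive segments to the log trapezoid.
#'
#' @param profile A [conc_time_profile()].
#' @param t_end End of integration (h); defaults to the last sample. Must not
#'   exceed the last sample and must not precede the first.
#' @param t_start Start of integration (h); defaults to the first sample.
#' @param method `"linear"` (default) or `"linlog"`.
#' @return AUC between `t_start` and `t_end` (ng·h/mL).
#' @examples
#' auc_trapezoid(conc_time_profile(c(0, 1), c(0, 2)))  # 1 ng·h/mL
#' @export
auc_trapezoid <- function(profile, t_end = NULL, t_start = NULL,
                          method = c("linear", "linlog")) {
  method <- match.arg(method)
  moment_auc(profile, t_end, t_start, method, weight_time = FALSE)
}

#' Trapezoidal first-moment area (AUMC)
#'
#' Linear trapezoidal integral of `t * C(t)`, the first moment of the curve,
#' used with the AUC to form the mean residence time.
#'
#' @inheritParams auc_trapezoid
#' @return AUMC between `t_start` and `t_end` (ng·h²/mL).
#' @export
aumc_trapezoid <- function(profile, t_end = NULL, t_start = NULL,
                           method = c("linear", "linlog")) {
  method <- match.arg(method)
  moment_auc(profile, t_end, t_start, method, weight_time = TRUE)
}

moment_auc <- function(profile, t_end, t_start, method, weight_time) {
  stopifnot(inherits(profile, "conc_time_profile"))
  tms <- profile$times
  t_start <- t_start %||% tms[1]
  t_end <- t_end %||% tms[length(tms)]
  if (t_end < tms[1]) stop_input("`t_end` precedes the first sample")
  if (t_end > tms[length(tms)]) {
    stop_input("`t_end` is beyond the last sample; use extrapolate_inf() past t_last")
  }
  if (t_start < tms[1] || t_start > t_end) {
    stop_input("`t_start` must lie within the sampled range, before `t_end`")
  }
  grid <- sort(unique(c(t_start, tms[tms > t_start & tms < t_end], t_end)))
  conc <- interp_conc(profile, grid)
  y <- if (weight_time) grid * conc else conc
  if (weight_time && method == "linlog") method <- "linear"  # moment kept linear
  total <- 0
  for (i in seq_len(length(grid) - 1)) {
    total <- total + trapezoid_area(grid[i], grid[i + 1], y[i], y[i + 1], method)
  }
  total
}

#' Terminal elimination rate constant (lambda_z)
#'
#' Log-linear regression on the terminal phase. Candidate point sets are the
#' last `k` positive-concentration samples strictly after Tmax, for `k` from 3
#' up to all post-Tmax points; the set maximising the adjusted R-squared is
#' selected (a set with more points wins when within 1e-4 of the best, the
#' usual automatic-selection convention). The regression is unweighted OLS on
#' `log(C)` versus `t`; the fitted slope must be negative, i.e. `lambda_z > 0`.
#'
#' @param profile A [conc_time_profile()].
#' @return A list: `lambda_z` (1/h), `n_points`, `adj_r_squared`,
#'   `points` (indices into the profile).
#' @examples
#' p <- conc_time_profile(c(0, 4, 6, 8, 10), c(0, 100 * exp(-0.2 * c(4, 6, 8, 10))))
#' terminal_slope(p)$lambda_z  # 0.2
#' @export
terminal_slope <- function(profile) {
  stopifnot(inherits(profile, "conc_time_profile"))
  tmx <- cmax_tmax(profile)$t_max
  idx <- which(profile$times > tmx & profile$concentrations > 0)
  if (length(idx) < 3) {
    abort("terminal phase undefined: fewer than 3 positive points after Tmax",
          class = c("ocukin_terminal_phase_undefined", "ocukin_error"))
  }
  fits <- list()
  for (k in seq(3, length(idx))) {
    cand <- tail(idx, k)
    fit <- ols_line(profile$times[cand], log(profile$concentrations[cand]))
    if (fit$slope >= 0) next
    fits[[length(fits) + 1L]] <- list(fit = fit, k = k, points = cand)
  }
  best <- NULL
  if (length(fits) > 0) {
    top <- max(vapply(fits, function(f) f$fit$adj_r_squared, numeric(1)))
    for (f in fits) {  # longest candidate within 1e-4 of the best fit wins
      if (f$fit$adj_r_squared >= top - 1e-4 &&
          (is.null(best) || f$k > best$k)) best <- f
    }
  }
  if (is.null(best)) {
    abort("terminal phase undefined: no candidate set gives a negative slope",
          class = c("ocukin_terminal_phase_undefined", "ocukin_error"))
  }
  list(lambda_z = -best$fit$slope, n_points = best$k,
       adj_r_squared = best$fit$adj_r_squared, points = best$points)
}

#' Extrapolate AUC and AUMC to infinite time
#'
#' Standard terminal-phase extrapolation:
#' `AUC(0-inf) = AUC(0-t) + C_last / lambda_z` and
#' `AUMC(0-inf) = AUMC(0-t) + C_last * t_last / lambda_z + C_last / lambda_z^2`.
#'
#' @param auc_0_t,aumc_0_t Observed areas up to the last quantifiable sample.
#' @param c_last Last quantifiable concentration (ng/mL), >= 0.
#' @param t_last Time of `c_last` (h).
#' @param lambda_z Terminal rate constant (1/h), > 0.
#' @return A list: `auc_0_inf`, `aumc_0_inf`, `auc_ratio` (= AUC0-t / AUC0-inf).
#' @examples
#' extrapolate_inf(90, 500, c_last = 2, t_last = 24, lambda_z = 0.2)
#' @export
extrapolate_inf <- function(auc_0_t, aumc_0_t, c_last, t_last, lambda_z) {
  check_numeric(auc_0_t, "auc_0_t", min = 0, len = 1)
  check_numeric(aumc_0_t, "aumc_0_t", min = 0, len = 1)
  check_numeric(c_last, "c_last", min = 0, len = 1)
  check_numeric(t_last, "t_last", min = 0, len = 1)
  if (!is.numeric(lambda_z) || length(lambda_z) != 1 || lambda_z <= 0) {
    stop_input("`lambda_z` must be a positive scalar")
  }
  auc_inf <- auc_0_t + c_last / lambda_z
  aumc_inf <- aumc_0_t + c_last * t_last / lambda_z + c_last / lambda_z^2
  list(auc_0_inf = auc_inf, aumc_0_inf = aumc_inf,
       auc_ratio = auc_0_t / auc_inf)
}

#' Full non-compartmental analysis of one profile
#'
#' Composes [cmax_tmax()], [auc_trapezoid()]/[aumc_trapezoid()],
#' [terminal_slope()] and [extrapolate_inf()] into the standard NCA parameter
#' set. If the profile carries an `loq`, concentrations below it are dropped
#' after the last quantifiable sample and treated as missing before it.
#'
#' @param profile A [conc_time_profile()].
#' @param method Trapezoid rule, `"linear"` (default) or `"linlog"`.
#' @return An object of class `nca_result` with fields `c_max`, `t_max`,
#'   `lambda_z`, `lambda_z_n`, `lambda_z_adj_r2`, `t_half`, `auc_0_t`,
#'   `auc_0_inf`, `auc_ratio`, `aumc_0_inf`, `mrt_0_inf`, `t_last`, `c_last`,
#'   plus the profile labels.
#' @examples
#' p <- gen_bateman_profile(bateman_params(noise_cv = 0), times = c(0:12, 16, 20, 24))
#' run_nca(p)
#' @export
run_nca <- function(profile, method = c("linear", "linlog")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_time_profile"))
  profile <- apply_loq(profile)
  n <- length(profile$times)
  if (n < 3) {
    abort("NCA needs at least 3 quantifiable samples",
          class = c("ocukin_insufficient_data", "ocukin_error"))
  }
  peak <- cmax_tmax(profile)
  t_last <- profile$times[n]
  c_last <- profile$concentrations[n]
  auc_t <- auc_trapezoid(profile, method = method)
  aumc_t <- aumc_trapezoid(profile, method = method)
  term <- terminal_slope(profile)
  ext <- extrapolate_inf(auc_t, aumc_t, c_last, t_last, term$lambda_z)
  structure(
    list(subject_id = profile$subject_id, formulation = profile$formulation,
         c_max = peak$c_max, t_max = peak$t_max,
         lambda_z = term$lambda_z, lambda_z_n = term$n_points,
         lambda_z_adj_r2 = term$adj_r_squared,
         t_half = log(2) / term$lambda_z,
         auc_0_t = auc_t, auc_0_inf = ext$auc_0_inf,
         auc_ratio = ext$auc_ratio, aumc_0_inf = ext$aumc_0_inf,
         mrt_0_inf = ext$aumc_0_inf / ext$auc_0_inf,
         t_last = t_last, c_last = c_last, method = method),
    class = "nca_result"
  )
}

# LOQ policy: censor sub-LOQ values before the last quantifiable sample
# (missing), truncate the profile after it.
apply_loq <- function(profile) {
  if (is.null(profile$loq)) return(profile)
  quant <- profile$concentrations >= profile$loq
  if (!any(quant)) {
    abort("no quantifiable samples at or above the LOQ",
          class = c("ocukin_insufficient_data", "ocukin_error"))
  }
  last_q <- max(which(quant))
  keep <- which(quant & seq_along(quant) <= last_q)
  conc_time_profile(profile$times[keep], profile$concentrations[keep],
                    subject_id = profile$subject_id,
                    formulation = profile$formulation)
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s / %s (%s trapezoid)\n",
              x$formulation, x$subject_id, x$method))
  cat(sprintf("  Cmax %s ng/mL at Tmax %g h; Clast %s ng/mL at %g h\n",
              fmt_num(x$c_max), x$t_max, fmt_num(x$c_last), x$t_last))
  cat(sprintf("  lambda_z %s 1/h (%d pts, adj R^2 %s); t1/2 %s h\n",
              fmt_num(x$lambda_z), x$lambda_z_n, fmt_num(x$lambda_z_adj_r2, 5),
              fmt_num(x$t_half)))
  cat(sprintf("  AUC0-t %s, AUC0-inf %s ng.h/mL (ratio %s); AUMC0-inf %s; MRT %s h\n",
              fmt_num(x$auc_0_t), fmt_num(x$auc_0_inf), fmt_num(x$auc_ratio, 3),
              fmt_num(x$aumc_0_inf), fmt_num(x$mrt_0_inf)))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id, formulation = x$formulation,
    c_max_ng_per_ml = x$c_max, t_max_h = x$t_max,
    lambda_z_per_h = x$lambda_z, lambda_z_n = x$lambda_z_n,
    lambda_z_adj_r2 = x$lambda_z_adj_r2, t_half_h = x$t_half,
    auc_0_t_ng_h_per_ml = x$auc_0_t, auc_0_inf_ng_h_per_ml = x$auc_0_inf,
    auc_ratio = x$auc_ratio, aumc_0_inf_ng_h2_per_ml = x$aumc_0_inf,
    mrt_0_inf_h = x$mrt_0_inf
  )
}

#' Fold change between two parameter values
#'
#' Matches the narrative convention of PK comparisons: with
#' `direction = "higher"` the result is `test / reference` ("x-fold greater"),
#' with `direction = "lower"` it is `reference / test` ("x-fold lower").
#'
#' @param test_value,ref_value Positive parameter values.
#' @param direction `"higher"` or `"lower"`.
#' @return The dimensionless fold change.
#' @examples
#' fold_change(5294.19, 2826.71, "higher")  # 1.87
#' fold_change(561.79, 809.26, "lower")     # 1.44
#' @export
fold_change <- function(test_value, ref_value, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  check_numeric(test_value, "test_value", len = 1)
  check_numeric(ref_value, "ref_value", len = 1)
  denom <- if (direction == "higher") ref_value else test_value
  if (denom <= 0) {
    abort("fold change undefined: denominator must be > 0",
          class = c("ocukin_undefined_ratio", "ocukin_error"))
  }
  if (direction == "higher") test_value / ref_value else ref_value / test_value
}

#' Average replicate profiles into per-formulation mean profiles
#'
#' Destructive (sparse) ocular sampling yields a few eyes per time point;
#' the standard treatment runs NCA on the mean concentration at each time.
#' Concentrations are averaged per formulation x time across subjects.
#'
#' @param data A data frame with columns `subject_id`, `formulation`,
#'   `time_h`, `conc_ng_per_ml`.
#' @param loq Optional LOQ attached to each mean profile.
#' @return A named list of [conc_time_profile()], one per formulation.
#' @export
mean_profiles <- function(data, loq = NULL) {
  need <- c("subject_id", "formulation", "time_h", "conc_ng_per_ml")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_input(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  means <- data |>
    dplyr::group_by(.data$formulation, .data$time_h) |>
    dplyr::summarise(conc = mean(.data$conc_ng_per_ml), .groups = "drop") |>
    dplyr::arrange(.data$formulation, .data$time_h)
  out <- lapply(split(means, means$formulation), function(d) {
    conc_time_profile(d$time_h, d$conc, subject_id = "mean",
                      formulation = d$formulation[1], loq = loq)
  })
  out
}
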