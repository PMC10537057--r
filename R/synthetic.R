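# Synthetic-data generators. Each generator draws from its own seeded RNG
# stream (withr::with_seed) so identical parameters give bit-identical output
# and the global RNG state is never touched.

#' Parameters for a Bateman aqueous-humor concentration profile
#'
#' One-compartment model with first-order absorption and first-order
#' elimination. The noise-free concentration at time `t` is
#' `A * (exp(-ke * t) - exp(-ka * t))` with `A = dose_over_volume * ka / (ka - ke)`.
#'
#' @param dose_over_volume Scaled dose `F*D/V` (ng/mL).
#' @param ka Absorption rate constant (1/h), > 0.
#' @param ke Elimination rate constant (1/h), > 0 and different from `ka`
#'   (the coincident-rate limit form is not modelled).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (0 for noise-free curves).
#' @param seed Integer RNG seed.
#' @return An object of class `bateman_params`.
#' @examples
#' bateman_params(dose_over_volume = 100, ka = 1, ke = 0.1)
#' @export
bateman_params <- function(dose_over_volume = 100, ka = 1, ke = 0.1,
                           noise_cv = 0, seed = 1L) {
  check_numeric(dose_over_volume, "dose_over_volume", min = 0, strict_min = TRUE, len = 1)
  check_numeric(ka, "ka", min = 0, strict_min = TRUE, len = 1)
  check_numeric(ke, "ke", min = 0, strict_min = TRUE, len = 1)
  if (ka == ke) {
    abort("`ka` must differ from `ke`: the coincident-rate Bateman limit is not supported",
          class = c("ocukin_degenerate_model", "ocukin_error"))
  }
  check_numeric(noise_cv, "noise_cv", min = 0, len = 1)
  structure(
    list(dose_over_volume = dose_over_volume, ka = ka, ke = ke,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = c("bateman_params", "ocukin_params")
  )
}

# Noise-free Bateman curve; vectorised over t.
bateman_conc <- function(params, t) {
  a <- params$dose_over_volume * params$ka / (params$ka - params$ke)
  a * (exp(-params$ke * t) - exp(-params$ka * t))
}

# Lognormal factors with unit mean and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an aqueous-humor concentration-time profile
#'
#' Evaluates the Bateman curve of `params` at `times` and applies
#' multiplicative lognormal noise (unit mean, CV = `noise_cv`) per point.
#'
#' @param params A [bateman_params()] object.
#' @param times Sampling times (h), sorted and nonnegative.
#' @param subject_id,formulation Labels carried into the profile.
#' @return A [conc_time_profile()].
#' @examples
#' p <- gen_bateman_profile(bateman_params(noise_cv = 0), times = 0:24)
#' max(p$concentrations)
#' @export
gen_bateman_profile <- function(params, times, subject_id = "sim",
                                formulation = "synthetic") {
  stopifnot(inherits(params, "bateman_params"))
  check_times(times)
  conc <- bateman_conc(params, times)
  noise <- withr::with_seed(params$seed, lognormal_noise(length(times), params$noise_cv))
  conc_time_profile(times, conc * noise,
                    subject_id = subject_id, formulation = formulation)
}

#' Parameters for a simulated dialysis-bag release experiment
#'
#' The true cumulative released fraction follows a Higuchi square-root law
#' with an instantaneous burst: `f(t) = min(1, burst_fraction + (k_h/100) * sqrt(t))`.
#' The measurement process is reproduced in full: at each sampling time an
#' aliquot of `sample_volume` mL is withdrawn and replaced with drug-free
#' medium, so later sampled concentrations under-report the cumulative
#' release unless the analysis corrects for the withdrawn mass.
#'
#' @param burst_fraction Fraction of the dose released instantaneously, in \[0, 1\].
#' @param k_h Higuchi release constant (percent per square-root hour).
#' @param medium_volume Release-medium (simulated tear fluid) volume (mL).
#' @param sample_volume Aliquot withdrawn per time point (mL), < `medium_volume`.
#' @param dose Drug amount loaded in the dialysis bag (µg).
#' @param times Sampling times (h), strictly increasing and positive.
#' @param noise_cv Lognormal CV applied to measured concentrations.
#' @param seed Integer RNG seed.
#' @return An object of class `release_sim_params`.
#' @export
release_sim_params <- function(burst_fraction = 0, k_h = 22,
                               medium_volume = 50, sample_volume = 1,
                               dose = 1000, times = c(0.5, 1, 2, 3, 4, 6, 8, 12),
                               noise_cv = 0, seed = 1L) {
  check_numeric(burst_fraction, "burst_fraction", min = 0, len = 1)
  if (burst_fraction > 1) stop_input("`burst_fraction` must be <= 1")
  check_numeric(k_h, "k_h", min = 0, len = 1)
  check_numeric(medium_volume, "medium_volume", min = 0, strict_min = TRUE, len = 1)
  check_numeric(sample_volume, "sample_volume", min = 0, len = 1)
  if (sample_volume >= medium_volume) {
    stop_input("`sample_volume` must be smaller than `medium_volume`")
  }
  check_numeric(dose, "dose", min = 0, strict_min = TRUE, len = 1)
  check_times(times)
  if (times[1] <= 0) stop_input("release sampling `times` must be positive")
  check_numeric(noise_cv, "noise_cv", min = 0, len = 1)
  structure(
    list(burst_fraction = burst_fraction, k_h = k_h,
         medium_volume = medium_volume, sample_volume = sample_volume,
         dose = dose, times = times, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = c("release_sim_params", "ocukin_params")
  )
}

#' Simulate a dialysis-bag release experiment with withdrawal/replacement
#'
#' Mass-balance bookkeeping per sampling event, under a well-mixed medium:
#' drug released since the previous sample distributes instantly in the
#' medium; the aliquot is withdrawn at the sampling instant and replaced with
#' drug-free medium. The returned experiment carries the generator's internal
#' truth (`true_percent`, noise-free cumulative release in percent and the
#' per-event mass ledger) so estimators can be validated against it.
#'
#' @param params A [release_sim_params()] object.
#' @return A [release_experiment()] with extra fields `true_percent` and
#'   `mass_ledger` (tibble: time, in_bag, in_medium, removed — µg).
#' @examples
#' exp <- gen_release_experiment(release_sim_params(noise_cv = 0))
#' exp$true_percent
#' @export
gen_release_experiment <- function(params) {
  stopifnot(inherits(params, "release_sim_params"))
  tms <- params$times
  f <- pmin(1, params$burst_fraction + (params$k_h / 100) * sqrt(tms))
  n <- length(tms)
  conc_true <- numeric(n)   # medium concentration at each sampling instant
  removed <- numeric(n)     # mass removed in each aliquot
  medium_mass <- 0
  f_prev <- 0
  for (i in seq_len(n)) {
    medium_mass <- medium_mass + (f[i] - f_prev) * params$dose
    conc_true[i] <- medium_mass / params$medium_volume
    removed[i] <- conc_true[i] * params$sample_volume
    medium_mass <- medium_mass - removed[i]
    f_prev <- f[i]
  }
  noise <- withr::with_seed(params$seed, lognormal_noise(n, params$noise_cv))
  exp <- release_experiment(
    times = tms,
    concentrations = conc_true * noise,
    dilution_factors = rep(1, n),
    sample_volume = params$sample_volume,
    medium_volume = params$medium_volume,
    dose = params$dose
  )
  exp$true_percent <- 100 * f
  exp$mass_ledger <- tibble::tibble(
    time_h = tms,
    in_bag = (1 - f) * params$dose,
    in_medium = params$dose * f - cumsum(removed),
    removed = cumsum(removed)
  )
  exp
}

#' Parameters for a simulated transcorneal permeation curve
#'
#' Noise-free cumulative permeated amount per unit area is lag-then-linear:
#' `Q(t) = max(0, flux * (t - t_lag))`; Gaussian noise is added per point and
#' monotonicity restored with a running maximum.
#'
#' @param flux True steady-state flux (µg cm^-2 h^-1), >= 0.
#' @param t_lag Lag time (h), >= 0.
#' @param times Sampling times (h), strictly increasing.
#' @param noise_sd Additive Gaussian noise SD (µg/cm²).
#' @param seed Integer RNG seed.
#' @return An object of class `permeation_sim_params`.
#' @export
permeation_sim_params <- function(flux = 17.81, t_lag = 0.25,
                                  times = c(0.5, 1, 2, 3, 4, 5, 6),
                                  noise_sd = 0, seed = 1L) {
  check_numeric(flux, "flux", min = 0, len = 1)
  check_numeric(t_lag, "t_lag", min = 0, len = 1)
  check_times(times)
  check_numeric(noise_sd, "noise_sd", min = 0, len = 1)
  structure(
    list(flux = flux, t_lag = t_lag, times = times,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = c("permeation_sim_params", "ocukin_params")
  )
}

#' Simulate a cumulative transcorneal permeation experiment
#'
#' @param params A [permeation_sim_params()] object.
#' @param c0 Donor concentration (µg/mL); default is the 0.1 percent w/v
#'   donor load used in corneal Franz-cell work.
#' @param area Exposed corneal cross-section (cm²).
#' @param label Formulation label.
#' @return A [permeation_experiment()].
#' @export
gen_permeation_experiment <- function(params, c0 = 500, area = 0.636,
                                      label = "synthetic") {
  stopifnot(inherits(params, "permeation_sim_params"))
  q_true <- pmax(0, params$flux * (params$times - params$t_lag))
  noise <- withr::with_seed(params$seed, rnorm(length(q_true), 0, params$noise_sd))
  q <- cummax(pmax(0, q_true + noise))
  permeation_experiment(params$times, q, c0 = c0, area = area, label = label)
}

# Endpoints an efficacy panel may carry; unit conventions in efficacy_panel().
EFFICACY_ENDPOINTS <- c("clinical_score", "cell_count", "protein",
                        "TNFa", "IL6", "MPO", "histo_score")

#' Parameters for a simulated efficacy panel
#'
#' Group-by-endpoint means and SDs with a common replicate count. Defaults
#' reproduce the published group summaries of the uveitis efficacy study this
#' package models (clinical score and aqueous-humor protein for the five
#' groups), with illustrative values for endpoints whose group means are only
#' published graphically.
#'
#' @param group_means,group_sds Numeric matrices (rows = groups,
#'   columns = endpoints, matching dimnames). Endpoint names must come from
#'   `clinical_score, cell_count, protein, TNFa, IL6, MPO, histo_score`.
#' @param n_per_group Replicates per group x endpoint, >= 1.
#' @param seed Integer RNG seed.
#' @return An object of class `efficacy_sim_params`.
#' @export
efficacy_sim_params <- function(group_means = default_efficacy_means(),
                                group_sds = default_efficacy_sds(),
                                n_per_group = 3, seed = 1L) {
  if (!is.matrix(group_means) || !is.matrix(group_sds)) {
    stop_input("`group_means` and `group_sds` must be matrices with dimnames")
  }
  if (!identical(dim(group_means), dim(group_sds)) ||
      !identical(dimnames(group_means), dimnames(group_sds))) {
    stop_input("`group_means` and `group_sds` must have identical dimnames")
  }
  bad <- setdiff(colnames(group_means), EFFICACY_ENDPOINTS)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown endpoint(s): %s", paste(bad, collapse = ", ")))
  }
  check_numeric(group_sds, "group_sds", min = 0)
  if (n_per_group < 1) stop_input("`n_per_group` must be >= 1")
  structure(
    list(group_means = group_means, group_sds = group_sds,
         n_per_group = as.integer(n_per_group), seed = as.integer(seed)),
    class = c("efficacy_sim_params", "ocukin_params")
  )
}

#' @rdname efficacy_sim_params
#' @export
default_efficacy_means <- function() {
  groups <- c("normal_control", "LIU", "DEX-AqS", "DEX-CSNPs", "HA-DEX-CSNPs")
  m <- rbind(
    # clinical score (0-4), protein (mg/mL): published group means.
    # TNFa/IL6/MPO (pg/mL) and cell_count (cells/mL): illustrative levels
    # consistent with the published percent reductions from the LIU group.
    normal_control  = c(0.00,  5.05,  40, 150, 100, 1.2e5),
    LIU             = c(3.732, 45.61, 400, 900, 800, 1.05e6),
    `DEX-AqS`       = c(2.670, 28.08, 347.2, 619.2, 610.4, 7.6e5),
    `DEX-CSNPs`     = c(1.578, 21.48, 137.6, 411.3, 484.8, 6.2e5),
    `HA-DEX-CSNPs`  = c(0.930, 16.27, 89.2, 393.3, 420.8, 4.9e5)
  )
  colnames(m) <- c("clinical_score", "protein", "TNFa", "IL6", "MPO", "cell_count")
  rownames(m) <- groups
  m
}

#' @rdname efficacy_sim_params
#' @export
default_efficacy_sds <- function() {
  m <- default_efficacy_means()
  s <- pmax(0.02 * m, 1e-3)           # ~2% relative scatter, n = 3 per group
  s[, "clinical_score"] <- c(0, 0.053, 0.085, 0.048, 0.053)
  s
}

#' Simulate an efficacy panel
#'
#' Replicate values are drawn Normal(mean, sd) per group x endpoint; grade
#' endpoints (`clinical_score`, `histo_score`) are clipped to the 0-4 grading
#' scale and counts/concentrations to nonnegative values.
#'
#' @param params An [efficacy_sim_params()] object.
#' @return An [efficacy_panel()].
#' @examples
#' panel <- gen_efficacy_panel(efficacy_sim_params(seed = 7))
#' summarize_groups(panel)
#' @export
gen_efficacy_panel <- function(params) {
  stopifnot(inherits(params, "efficacy_sim_params"))
  groups <- rownames(params$group_means)
  endpoints <- colnames(params$group_means)
  n <- params$n_per_group
  draws <- withr::with_seed(params$seed, {
    out <- list()
    for (g in groups) {
      for (ep in endpoints) {
        v <- rnorm(n, params$group_means[g, ep], params$group_sds[g, ep])
        v <- pmax(v, 0)
        if (ep %in% c("clinical_score", "histo_score")) v <- pmin(v, 4)
        out[[length(out) + 1L]] <- tibble::tibble(
          group = g, endpoint = ep, replicate = seq_len(n), value = v
        )
      }
    }
    dplyr::bind_rows(out)
  })
  efficacy_panel(draws)
}
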