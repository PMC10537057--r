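# Closed-form oracles for the one-compartment first-order absorption model
# (kept independent of the package's estimators).

bateman_closed <- function(t, dv, ka, ke) {
  dv * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# Antiderivative-based AUC of the Bateman curve on [0, t].
bateman_auc_closed <- function(t, dv, ka, ke) {
  dv * ka / (ka - ke) * ((1 - exp(-ke * t)) / ke - (1 - exp(-ka * t)) / ka)
}

bateman_auc_inf_closed <- function(dv, ka, ke) dv / ke

bateman_tmax_closed <- function(ka, ke) log(ka / ke) / (ka - ke)

bateman_mrt_closed <- function(ka, ke) 1 / ka + 1 / ke

# Brute-force mass-balance simulator for withdraw-and-replace sampling,
# written independently of gen_release_experiment(): full ledger per event.
brute_force_sampling <- function(frac_released, dose, medium_volume, sample_volume) {
  n <- length(frac_released)
  conc <- numeric(n)
  medium <- 0
  released_prev <- 0
  for (i in seq_len(n)) {
    medium <- medium + (frac_released[i] - released_prev) * dose
    conc[i] <- medium / medium_volume
    medium <- medium - conc[i] * sample_volume
    released_prev <- frac_released[i]
  }
  conc
}

dense_bateman_profile <- function(dv = 100, ka = 1, ke = 0.1, t_end = 48,
                                  by = 0.01) {
  gen_bateman_profile(
    bateman_params(dose_over_volume = dv, ka = ka, ke = ke, noise_cv = 0),
    times = seq(0, t_end, by = by)
  )
}
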