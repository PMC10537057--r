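make_exp <- function(conc, df = 1, vs = 1, vm = 50, dose = 1000,
                     times = seq_along(conc)) {
  release_experiment(times, conc, dilution_factors = df, sample_volume = vs,
                     medium_volume = vm, dose = dose)
}

test_that("uncorrected percent released is direct substitution", {
  expect_equal(percent_released_eq1(make_exp(10))$percent_released, 50)
  expect_equal(percent_released_eq1(make_exp(0))$percent_released, 0)
  expect_equal(percent_released_eq1(make_exp(2, df = 5))$percent_released, 50)
})

test_that("withdrawal-corrected estimator adds back the sampled mass", {
  exp2 <- make_exp(c(10, 10), vs = 1)
  expect_equal(percent_released_corrected(exp2)$percent_released, c(50, 51))
  # with no withdrawal the two estimators coincide
  exp0 <- make_exp(c(4, 7, 9), vs = 0)
  expect_equal(percent_released_corrected(exp0)$percent_released,
               percent_released_eq1(exp0)$percent_released)
  expect_identical(attr(percent_released_corrected(exp2), "estimator"),
                   "withdrawal_corrected")
  expect_identical(attr(percent_released_eq1(exp2), "estimator"),
                   "verbatim_eq1")
})

test_that("corrected estimator inverts the generator's sampling distortion", {
  par <- release_sim_params(burst_fraction = 0.1, k_h = 24, sample_volume = 2,
                            medium_volume = 50, dose = 1200,
                            times = c(0.5, 1, 2, 3, 4, 6, 8, 12), noise_cv = 0)
  e <- gen_release_experiment(par)
  rec <- percent_released_corrected(e)$percent_released
  expect_equal(rec, e$true_percent, tolerance = 1e-6)
  # the uncorrected estimator underestimates strictly once mass has been removed
  eq1 <- percent_released_eq1(e)$percent_released
  expect_true(all(rec[-1] > eq1[-1]))
  expect_equal(rec[1], eq1[1])
})

test_that("corrected never falls below uncorrected across random experiments", {
  for (seed in 1:10) {
    par <- release_sim_params(burst_fraction = 0.1, k_h = 15,
                              sample_volume = 1.5, dose = 900,
                              times = c(1, 2, 4, 8), noise_cv = 0.2, seed = seed)
    e <- gen_release_experiment(par)
    expect_true(all(percent_released_corrected(e)$percent_released >=
                      percent_released_eq1(e)$percent_released - 1e-12))
  }
})

test_that("release above the nominal dose warns but is kept", {
  e <- make_exp(c(10, 25), vs = 0)  # 125% at the second sample
  expect_warning(curve <- percent_released_eq1(e), class = "ocukin_over_release")
  expect_equal(curve$percent_released[2], 125)
})

test_that("Higuchi fit recovers an exact square-root line", {
  curve <- tibble::tibble(times = c(1, 4, 9),
                          percent_released = 25 * sqrt(c(1, 4, 9)))
  fit <- fit_higuchi(curve)
  expect_equal(fit$k_h, 25, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  flat <- tibble::tibble(times = c(1, 2, 3), percent_released = c(40, 40, 40))
  expect_equal(fit_higuchi(flat)$k_h, 0, tolerance = 1e-12)
})

test_that("Higuchi fit is invariant to point order and intercept convention is honoured", {
  curve <- tibble::tibble(times = c(1, 2, 4, 9),
                          percent_released = c(24, 36, 51, 77))
  shuffled <- curve[c(3, 1, 4, 2), ]
  expect_equal(fit_higuchi(curve)$k_h, fit_higuchi(shuffled)$k_h)
  expect_equal(fit_higuchi(curve)$r_squared, fit_higuchi(shuffled)$r_squared)
  no_int <- fit_higuchi(curve, fit_intercept = FALSE)
  expect_identical(no_int$intercept, 0)
  expect_true(no_int$r_squared >= 0 && no_int$r_squared <= 1)
})

test_that("reported sustained-release points lie on a square-root line", {
  pts <- read.csv(system.file("extdata", "release_reported_points.csv",
                              package = "ocukin"))
  ha <- pts[pts$formulation == "HA-DEX-CSNPs", ]
  fit <- fit_higuchi(tibble::tibble(times = ha$time_h,
                                    percent_released = ha$percent_released))
  expect_gte(fit$r_squared, 0.95)
  # the burst-release formulation deviates more from square-root kinetics
  un <- pts[pts$formulation == "DEX-CSNPs", ]
  fit_un <- fit_higuchi(tibble::tibble(times = un$time_h,
                                       percent_released = un$percent_released))
  expect_lt(fit_un$r_squared, fit$r_squared)
})

test_that("noise-free synthetic Higuchi release returns the generating constant", {
  par <- release_sim_params(burst_fraction = 0, k_h = 22, sample_volume = 1,
                            times = c(0.5, 1, 2, 3, 4, 6, 8, 12), noise_cv = 0)
  e <- gen_release_experiment(par)
  fit <- fit_higuchi(percent_released_corrected(e))
  expect_equal(fit$k_h, 22, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("degenerate release inputs are rejected", {
  expect_error(make_exp(c(1, 2), dose = 0), class = "ocukin_input_error")
  expect_error(release_experiment(c(1, 1), c(2, 2), sample_volume = 0, dose = 10),
               class = "ocukin_input_error")
  expect_error(fit_higuchi(tibble::tibble(times = c(1, 2),
                                          percent_released = c(1, 2))),
               class = "ocukin_insufficient_data")
})
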