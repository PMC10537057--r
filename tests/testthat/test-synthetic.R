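test_that("noise-free Bateman generator matches the closed form everywhere", {
  tms <- seq(0, 48, by = 0.25)
  p <- gen_bateman_profile(bateman_params(dose_over_volume = 100, ka = 1,
                                          ke = 0.1, noise_cv = 0), tms)
  expect_equal(p$concentrations, bateman_closed(tms, 100, 1, 0.1),
               tolerance = 1e-12)
  expect_identical(p$concentrations[1], 0)          # vanishes at t = 0
})

test_that("Bateman curve peaks where the grid-search oracle says", {
  grid <- seq(0, 10, by = 1e-4)
  oracle_tmax <- grid[which.max(bateman_closed(grid, 100, 1, 0.1))]
  p <- gen_bateman_profile(bateman_params(noise_cv = 0), grid)
  expect_equal(cmax_tmax(p)$t_max, oracle_tmax, tolerance = 1e-8)
  expect_equal(oracle_tmax, 2.5584, tolerance = 1e-4)
})

test_that("Bateman curve integrates to dose_over_volume / ke", {
  # fine-grid numeric integration to 120 h plus the analytic tail
  tms <- seq(0, 120, by = 0.01)
  c_t <- bateman_closed(tms, 100, 1, 0.1)
  numeric_auc <- sum(diff(tms) * (head(c_t, -1) + tail(c_t, -1)) / 2) +
    c_t[length(c_t)] / 0.1
  expect_equal(numeric_auc, 1000, tolerance = 1e-4)
  expect_equal(bateman_auc_inf_closed(100, 1, 0.1), 1000)
})

test_that("generators are bit-reproducible under a fixed seed and leave the global RNG alone", {
  set.seed(99)
  before <- .Random.seed
  p1 <- gen_bateman_profile(bateman_params(noise_cv = 0.2, seed = 7), 0:24)
  e1 <- gen_release_experiment(release_sim_params(noise_cv = 0.1, seed = 7))
  q1 <- gen_permeation_experiment(permeation_sim_params(noise_sd = 1, seed = 7))
  f1 <- gen_efficacy_panel(efficacy_sim_params(seed = 7))
  expect_identical(before, .Random.seed)
  p2 <- gen_bateman_profile(bateman_params(noise_cv = 0.2, seed = 7), 0:24)
  e2 <- gen_release_experiment(release_sim_params(noise_cv = 0.1, seed = 7))
  q2 <- gen_permeation_experiment(permeation_sim_params(noise_sd = 1, seed = 7))
  f2 <- gen_efficacy_panel(efficacy_sim_params(seed = 7))
  expect_identical(p1$concentrations, p2$concentrations)
  expect_identical(e1$concentrations, e2$concentrations)
  expect_identical(q1$q_cumulative, q2$q_cumulative)
  expect_identical(f1$value, f2$value)
  # different seeds give different noise
  p3 <- gen_bateman_profile(bateman_params(noise_cv = 0.2, seed = 8), 0:24)
  expect_false(identical(p1$concentrations, p3$concentrations))
})

test_that("coincident absorption and elimination rates are rejected", {
  expect_error(bateman_params(ka = 0.5, ke = 0.5),
               class = "ocukin_degenerate_model")
})

test_that("release generator reduces to truth / dose ratio without withdrawal", {
  par <- release_sim_params(burst_fraction = 0, k_h = 25, sample_volume = 0,
                            dose = 1000, medium_volume = 50,
                            times = c(1, 2, 4), noise_cv = 0)
  e <- gen_release_experiment(par)
  f <- pmin(1, 0.25 * sqrt(par$times))
  expect_equal(e$concentrations, f * 1000 / 50, tolerance = 1e-12)
  expect_equal(e$concentrations[3], 10)   # f(4 h) = 0.5 -> 500 ug in 50 mL
})

test_that("withdrawal depresses later sampled concentrations below the no-withdrawal case", {
  times <- c(0.5, 1, 2, 3, 4, 6, 8, 12)
  with_wd <- gen_release_experiment(release_sim_params(
    k_h = 25, sample_volume = 1, medium_volume = 50, times = times, noise_cv = 0))
  no_wd <- gen_release_experiment(release_sim_params(
    k_h = 25, sample_volume = 0, medium_volume = 50, times = times, noise_cv = 0))
  expect_true(all(with_wd$concentrations[-1] < no_wd$concentrations[-1]))
  # and agrees with an independent brute-force ledger of the sampling process
  oracle <- brute_force_sampling(0.25 * sqrt(times), 1000, 50, 1)
  expect_equal(with_wd$concentrations, oracle, tolerance = 1e-12)
})

test_that("release generator conserves mass at every sampling event", {
  for (seed in 1:5) {
    par <- release_sim_params(burst_fraction = 0.2, k_h = 20, sample_volume = 2,
                              medium_volume = 50, dose = 800,
                              times = c(0.5, 1, 2, 4, 8, 12), noise_cv = 0,
                              seed = seed)
    e <- gen_release_experiment(par)
    ledger <- e$mass_ledger
    total <- ledger$in_bag + ledger$in_medium + ledger$removed
    expect_equal(total, rep(800, nrow(ledger)), tolerance = 1e-9)
    expect_true(all(e$true_percent <= 100))
  }
})

test_that("permeation generator follows the lag-then-linear form", {
  par <- permeation_sim_params(flux = 5, t_lag = 0.4, times = c(0.2, 0.3, 1, 2),
                               noise_sd = 0)
  e <- gen_permeation_experiment(par)
  expect_equal(e$q_cumulative[1:2], c(0, 0))       # before the lag
  expect_equal(e$q_cumulative[4], 8)               # 5 * (2 - 0.4)
  noisy <- gen_permeation_experiment(permeation_sim_params(noise_sd = 2, seed = 3))
  expect_true(all(diff(noisy$q_cumulative) >= 0))  # cumulative-max enforced
  expect_true(all(noisy$q_cumulative >= 0))
})

test_that("efficacy generator reproduces group structure", {
  zero_sd <- efficacy_sim_params(
    group_means = matrix(c(2, 10), 1, 2,
                         dimnames = list("LIU", c("clinical_score", "protein"))),
    group_sds = matrix(0, 1, 2,
                       dimnames = list("LIU", c("clinical_score", "protein"))),
    n_per_group = 3
  )
  panel <- gen_efficacy_panel(zero_sd)
  expect_equal(panel$value[panel$endpoint == "clinical_score"], rep(2, 3))
  expect_equal(panel$value[panel$endpoint == "protein"], rep(10, 3))
})

test_that("large-n draws concentrate on the generating mean", {
  n <- 1e4
  par <- efficacy_sim_params(
    group_means = matrix(50, 1, 1, dimnames = list("LIU", "protein")),
    group_sds = matrix(1, 1, 1, dimnames = list("LIU", "protein")),
    n_per_group = n, seed = 11
  )
  panel <- gen_efficacy_panel(par)
  expect_lt(abs(mean(panel$value) - 50), 3 / sqrt(n))
})

test_that("grade draws respect the 0-4 scale", {
  par <- efficacy_sim_params(
    group_means = matrix(3.9, 1, 1, dimnames = list("LIU", "clinical_score")),
    group_sds = matrix(1, 1, 1, dimnames = list("LIU", "clinical_score")),
    n_per_group = 500, seed = 5
  )
  panel <- gen_efficacy_panel(par)
  expect_true(all(panel$value <= 4 & panel$value >= 0))
})

test_that("unknown endpoint names are rejected", {
  expect_error(
    efficacy_sim_params(
      group_means = matrix(1, 1, 1, dimnames = list("LIU", "CRP")),
      group_sds = matrix(0, 1, 1, dimnames = list("LIU", "CRP"))
    ),
    class = "ocukin_input_error"
  )
})
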