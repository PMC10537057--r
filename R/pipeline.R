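# Configured end-to-end pipeline: simulate -> release -> permeation -> nca ->
# efficacy -> report, with tidy CSV interchange, stage-level logging and a
# reproducibility manifest.

PIPELINE_STAGES <- c("simulate", "release", "permeation", "nca", "efficacy", "report")

default_config <- function() {
  list(
    seed = 1L,
    outdir = "ocukin-out",
    stages = PIPELINE_STAGES,
    inputs = list(release_csv = NULL, permeation_csv = NULL,
                  ah_csv = NULL, efficacy_csv = NULL),
    constants = list(medium_volume = 50, dose = 1000, sample_volume = 1,
                     c0 = 500, area = 0.636, receptor_volume = 6.9),
    options = list(estimator = "corrected", fit_intercept = TRUE,
                   flux_window = NULL, lambda_z = "auto",
                   trapezoid = "linear",
                   reference_formulation = "DEX-AqS",
                   reference_group_reduction = "LIU",
                   reference_group_increase = "normal_control")
  )
}

merge_known <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop_input(sprintf("unknown %s key(s): %s", where,
                       paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) base[k] <- list(user[[k]])  # keeps explicit NULLs
  base
}

#' Build and validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills defaults, rejects
#' unknown keys, and validates stages, constants and input paths before
#' anything runs.
#'
#' Top-level keys: `seed`, `outdir`, `stages`, `inputs` (`release_csv`,
#' `permeation_csv`, `ah_csv`, `efficacy_csv`), `constants` (`medium_volume`,
#' `dose`, `sample_volume`, `c0`, `area`, `receptor_volume`) and `options`
#' (`estimator` = eq1|corrected, `fit_intercept`, `flux_window`,
#' `lambda_z` = auto, `trapezoid` = linear|linlog, and the three reference
#' labels). When `simulate` is not among the stages, every requested analysis
#' stage must point at an existing input CSV.
#'
#' @param path Path to a YAML config file, or `NULL`.
#' @param config A named list merged over the file (and over the defaults).
#' @return A validated list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(config = list(seed = 7, outdir = tempfile()))
#' cfg$seed
#' @export
pipeline_config <- function(path = NULL, config = list()) {
  base <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
    file_cfg <- yaml::read_yaml(path)
    base <- merge_nested(base, file_cfg)
  }
  cfg <- merge_nested(base, config)
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  for (k in names(cfg$constants)) {
    v <- cfg$constants[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop_input(sprintf("constant `%s` must be a nonnegative number", k))
    }
  }
  for (k in c("medium_volume", "dose", "c0", "area", "receptor_volume")) {
    if (cfg$constants[[k]] <= 0) stop_input(sprintf("constant `%s` must be > 0", k))
  }
  if (!cfg$options$estimator %in% c("eq1", "corrected")) {
    stop_input("options$estimator must be 'eq1' or 'corrected'")
  }
  if (!cfg$options$trapezoid %in% c("linear", "linlog")) {
    stop_input("options$trapezoid must be 'linear' or 'linlog'")
  }
  simulating <- "simulate" %in% cfg$stages
  needs <- c(release = "release_csv", permeation = "permeation_csv",
             nca = "ah_csv", efficacy = "efficacy_csv")
  if (!simulating) {
    for (stage in intersect(names(needs), cfg$stages)) {
      p <- cfg$inputs[[needs[[stage]]]]
      if (is.null(p)) {
        stop_input(sprintf("stage `%s` needs inputs$%s (or a simulate stage)",
                           stage, needs[[stage]]))
      }
      if (!file.exists(p)) stop_input(sprintf("input file not found: %s", p))
    }
  }
  structure(cfg, class = "pipeline_config")
}

merge_nested <- function(base, user) {
  user <- user %||% list()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop_input(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_known(base[[k]], user[[k]] %||% list(), k)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

# Simulation scenario used by the `simulate` stage: three formulations with
# release, permeation and aqueous-humor kinetics on the scale reported for
# topical dexamethasone nanoparticle studies, plus the five-group efficacy
# panel. Per-stream seeds are derived additively from the pipeline seed.
demo_scenario <- function(seed, constants) {
  list(
    release = release_sim_params(
      burst_fraction = 0, k_h = 22,
      medium_volume = constants$medium_volume,
      sample_volume = constants$sample_volume,
      dose = constants$dose,
      times = c(0.5, 1, 2, 3, 4, 6, 8, 12),
      noise_cv = 0.03, seed = seed + 101L
    ),
    permeation = list(
      `DEX-AqS` = permeation_sim_params(flux = 1.76, t_lag = 0.1,
                                        noise_sd = 0.15, seed = seed + 201L),
      `DEX-CSNPs` = permeation_sim_params(flux = 8.27, t_lag = 0.2,
                                          noise_sd = 0.4, seed = seed + 202L),
      `HA-DEX-CSNPs` = permeation_sim_params(flux = 17.81, t_lag = 0.3,
                                             noise_sd = 0.6, seed = seed + 203L)
    ),
    ah = list(
      `DEX-AqS` = bateman_params(
        dose_over_volume = dv_for_cmax(809.26, ka = 1.2, ke = log(2) / 2.18),
        ka = 1.2, ke = log(2) / 2.18, noise_cv = 0.08, seed = seed + 301L
      ),
      `DEX-CSNPs` = bateman_params(
        dose_over_volume = dv_for_cmax(561.79, ka = 0.35, ke = log(2) / 5.44),
        ka = 0.35, ke = log(2) / 5.44, noise_cv = 0.08, seed = seed + 302L
      ),
      `HA-DEX-CSNPs` = bateman_params(
        dose_over_volume = dv_for_cmax(584.32, ka = 0.30, ke = log(2) / 7.34),
        ka = 0.30, ke = log(2) / 7.34, noise_cv = 0.08, seed = seed + 303L
      )
    ),
    ah_times = c(0.5, 1, 2, 4, 6, 8, 12, 24),
    efficacy = efficacy_sim_params(seed = seed + 401L)
  )
}

# Scaled dose giving a target peak concentration for a Bateman curve.
dv_for_cmax <- function(cmax, ka, ke) {
  tmax <- log(ka / ke) / (ka - ke)
  unit_peak <- ka / (ka - ke) * (exp(-ke * tmax) - exp(-ka * tmax))
  cmax / unit_peak
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in order
#' (simulate, release, permeation, nca, efficacy, report), writing each
#' stage's tidy CSV outputs, a stage-level log and a reproducibility manifest
#' under `outdir`. Re-running with an identical configuration and seed
#' reproduces identical numeric outputs.
#'
#' @param config A [pipeline_config()], a path to a YAML config, or a named
#'   list of overrides.
#' @return The run manifest (class `run_manifest`): tool version, config
#'   hash, seed, timestamps and per-stage output files. Also written as
#'   `manifest.json`.
#' @examples
#' \donttest{
#' manifest <- run_pipeline(list(outdir = tempfile("ocukin"), seed = 7))
#' manifest$outputs$nca
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) {
    config
  } else if (is.character(config)) {
    pipeline_config(path = config)
  } else {
    pipeline_config(config = config)
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  log_add <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  log_add("ocukin %s | seed %d | outdir %s", packageVersion("ocukin"),
          cfg$seed, cfg$outdir)
  outputs <- list()
  inputs <- cfg$inputs
  scn <- demo_scenario(cfg$seed, cfg$constants)
  for (stage in intersect(PIPELINE_STAGES, cfg$stages)) {
    log_add("stage %s: start", stage)
    res <- tryCatch(
      switch(stage,
        simulate = stage_simulate(cfg, scn),
        release = stage_release(cfg, inputs$release_csv),
        permeation = stage_permeation(cfg, inputs$permeation_csv),
        nca = stage_nca(cfg, inputs$ah_csv),
        efficacy = stage_efficacy(cfg, inputs$efficacy_csv),
        report = list(files = make_report(cfg$outdir))
      ),
      error = function(e) {
        abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
              class = c("ocukin_stage_error", "ocukin_error"))
      }
    )
    if (stage == "simulate") inputs <- merge_known(inputs, res$inputs, "inputs")
    outputs[[stage]] <- res$files
    for (f in res$files) log_add("stage %s: wrote %s", stage, f)
  }
  manifest <- structure(
    list(tool = "ocukin", version = as.character(packageVersion("ocukin")),
         config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
         started = started, finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = outputs),
    class = "run_manifest"
  )
  jsonlite::write_json(unclass(manifest), file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$outdir, "pipeline.log"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> ocukin %s, seed %d, config %s\n",
              x$version, x$seed, substr(x$config_hash, 1, 10)))
  for (stage in names(x$outputs)) {
    cat(sprintf("  %s: %s\n", stage,
                paste(basename(unlist(x$outputs[[stage]])), collapse = ", ")))
  }
  invisible(x)
}

stage_simulate <- function(cfg, scn) {
  simdir <- file.path(cfg$outdir, "sim")
  dir.create(simdir, recursive = TRUE, showWarnings = FALSE)
  rel <- gen_release_experiment(scn$release)
  f_rel <- write_output_csv(
    data.frame(time_h = rel$times, conc_ug_per_ml = rel$concentrations,
               dilution_factor = rel$dilution_factors),
    file.path(simdir, "release.csv")
  )
  perm <- dplyr::bind_rows(lapply(names(scn$permeation), function(lab) {
    e <- gen_permeation_experiment(scn$permeation[[lab]],
                                   c0 = cfg$constants$c0,
                                   area = cfg$constants$area, label = lab)
    data.frame(formulation = lab, time_h = e$times, q_ug_per_cm2 = e$q_cumulative)
  }))
  f_perm <- write_output_csv(perm, file.path(simdir, "permeation.csv"))
  ah <- dplyr::bind_rows(lapply(names(scn$ah), function(lab) {
    p <- gen_bateman_profile(scn$ah[[lab]], scn$ah_times,
                             subject_id = "mean", formulation = lab)
    as.data.frame(p)
  }))
  f_ah <- write_output_csv(ah, file.path(simdir, "ah.csv"))
  panel <- gen_efficacy_panel(scn$efficacy)
  f_eff <- write_output_csv(as.data.frame(panel), file.path(simdir, "efficacy.csv"))
  list(files = c(f_rel, f_perm, f_ah, f_eff),
       inputs = list(release_csv = f_rel, permeation_csv = f_perm,
                     ah_csv = f_ah, efficacy_csv = f_eff))
}

stage_release <- function(cfg, path) {
  exp <- read_release_csv(path, sample_volume = cfg$constants$sample_volume,
                          medium_volume = cfg$constants$medium_volume,
                          dose = cfg$constants$dose)
  eq1 <- percent_released_eq1(exp)
  corr <- percent_released_corrected(exp)
  curves <- data.frame(time_h = exp$times,
                       percent_released_eq1 = eq1$percent_released,
                       percent_released_corrected = corr$percent_released)
  chosen <- if (cfg$options$estimator == "eq1") eq1 else corr
  fit <- fit_higuchi(chosen, fit_intercept = isTRUE(cfg$options$fit_intercept))
  fits <- data.frame(estimator = attr(chosen, "estimator"),
                     k_h_pct_per_sqrt_h = fit$k_h, intercept_pct = fit$intercept,
                     r_squared = fit$r_squared, n_points = fit$n)
  list(files = c(
    write_output_csv(curves, file.path(cfg$outdir, "release_curves.csv")),
    write_output_csv(fits, file.path(cfg$outdir, "release_higuchi.csv"))
  ))
}

stage_permeation <- function(cfg, path) {
  exps <- read_permeation_csv(path, c0 = cfg$constants$c0,
                              area = cfg$constants$area)
  window <- cfg$options$flux_window
  if (!is.null(window)) window <- as.numeric(window)
  results <- lapply(exps, steady_state_flux, window = window)
  ref_lab <- cfg$options$reference_formulation
  ref <- if (ref_lab %in% names(results)) results[[ref_lab]] else NULL
  d <- dplyr::bind_rows(lapply(results, function(r) {
    data.frame(
      formulation = r$label,
      flux_j_ug_per_cm2_per_h = r$flux_j,
      p_app_cm_per_h = r$p_app,
      t_lag_h = r$t_lag,
      r_squared = r$r_squared,
      enhancement_ratio = if (!is.null(ref) && r$label != ref_lab) {
        enhancement_ratio(r, ref)
      } else NA_real_
    )
  }))
  list(files = write_output_csv(d, file.path(cfg$outdir, "permeation_summary.csv")))
}

stage_nca <- function(cfg, path) {
  ah <- read_ah_csv(path)
  profiles <- mean_profiles(ah)
  results <- lapply(profiles, run_nca, method = cfg$options$trapezoid)
  params <- dplyr::bind_rows(lapply(results, as.data.frame))
  f_params <- write_output_csv(params, file.path(cfg$outdir, "nca_parameters.csv"))
  ref_lab <- cfg$options$reference_formulation
  folds <- NULL
  if (ref_lab %in% names(results)) {
    ref <- results[[ref_lab]]
    comparisons <- list(
      c(field = "auc_0_t", unit = "ng_h_per_ml", direction = "higher"),
      c(field = "auc_0_inf", unit = "ng_h_per_ml", direction = "higher"),
      c(field = "t_half", unit = "h", direction = "higher"),
      c(field = "mrt_0_inf", unit = "h", direction = "higher"),
      c(field = "c_max", unit = "ng_per_ml", direction = "lower")
    )
    folds <- dplyr::bind_rows(lapply(setdiff(names(results), ref_lab), function(lab) {
      dplyr::bind_rows(lapply(comparisons, function(cmp) {
        data.frame(
          parameter = cmp[["field"]], unit = cmp[["unit"]],
          test_formulation = lab, reference_formulation = ref_lab,
          direction = cmp[["direction"]],
          fold = fold_change(results[[lab]][[cmp[["field"]]]],
                             ref[[cmp[["field"]]]], cmp[["direction"]])
        )
      }))
    }))
  }
  files <- f_params
  if (!is.null(folds)) {
    files <- c(files, write_output_csv(folds, file.path(cfg$outdir, "nca_fold_changes.csv")))
  }
  list(files = files)
}

stage_efficacy <- function(cfg, path) {
  panel <- read_efficacy_csv(path)
  summaries <- summarize_groups(panel)
  f_sum <- write_output_csv(summaries, file.path(cfg$outdir, "efficacy_summary.csv"))
  ref_red <- cfg$options$reference_group_reduction
  ref_inc <- cfg$options$reference_group_increase
  changes <- dplyr::bind_rows(lapply(unique(summaries$endpoint), function(ep) {
    s <- summaries[summaries$endpoint == ep, ]
    ref_mean <- s$mean[s$group == ref_red]
    ctl_mean <- s$mean[s$group == ref_inc]
    dplyr::bind_rows(
      if (length(ref_mean) == 1 && ref_mean > 0) {
        d <- s[!s$group %in% c(ref_red, ref_inc), ]
        data.frame(endpoint = ep, group = d$group, comparison = "reduction_vs_disease",
                   reference = ref_red,
                   percent = percent_reduction(ref_mean, d$mean))
      },
      if (length(ctl_mean) == 1 && ctl_mean > 0 && length(ref_mean) == 1) {
        data.frame(endpoint = ep, group = ref_red, comparison = "increase_vs_control",
                   reference = ref_inc,
                   percent = percent_increase(ctl_mean, ref_mean))
      }
    )
  }))
  f_chg <- write_output_csv(changes, file.path(cfg$outdir, "efficacy_percent_change.csv"))
  tests <- dplyr::bind_rows(lapply(unique(summaries$endpoint), function(ep) {
    cmp <- tryCatch(compare_groups(panel, ep, reference = ref_red),
                    error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    data.frame(endpoint = ep, anova_f = cmp$anova$f_value,
               anova_p = cmp$anova$p_value, group = cmp$pairwise$group,
               t_p_value = cmp$pairwise$t_p_value,
               significant = cmp$pairwise$significant)
  }))
  f_tst <- write_output_csv(tests, file.path(cfg$outdir, "efficacy_tests.csv"))
  list(files = c(f_sum, f_chg, f_tst))
}

#' Assemble report tables from stage outputs
#'
#' Reads whichever stage outputs are present under `outdir` and writes
#' wide report tables: a corneal-permeation parameter table (flux,
#' enhancement ratio, apparent permeability by formulation), a
#' pharmacokinetic parameter table (nine NCA parameters by formulation) and a
#' combined fold-change / percent-change summary. Unit strings are carried in
#' the row labels, taken from the unit-suffixed column names of the stage
#' outputs; a stage file without its expected unit-suffixed columns is
#' rejected rather than merged.
#'
#' @param outdir Directory holding stage outputs.
#' @return Character vector of written report files.
#' @export
make_report <- function(outdir) {
  files <- character()
  perm_path <- file.path(outdir, "permeation_summary.csv")
  nca_path <- file.path(outdir, "nca_parameters.csv")
  fold_path <- file.path(outdir, "nca_fold_changes.csv")
  chg_path <- file.path(outdir, "efficacy_percent_change.csv")
  if (!file.exists(perm_path) && !file.exists(nca_path)) {
    stop_input("no stage outputs found to report on")
  }
  if (file.exists(perm_path)) {
    d <- read.csv(perm_path)
    need <- c("formulation", "flux_j_ug_per_cm2_per_h", "p_app_cm_per_h",
              "t_lag_h", "enhancement_ratio")
    if (!all(need %in% names(d))) {
      stop_input("permeation_summary.csv lacks the expected unit-labelled columns")
    }
    wide <- data.frame(
      parameter = c("steady_state_flux_ug_per_cm2_per_h", "enhancement_ratio",
                    "p_app_cm_per_h", "t_lag_h"),
      check.names = FALSE
    )
    for (i in seq_len(nrow(d))) {
      wide[[d$formulation[i]]] <- c(d$flux_j_ug_per_cm2_per_h[i],
                                    d$enhancement_ratio[i],
                                    d$p_app_cm_per_h[i], d$t_lag_h[i])
    }
    files <- c(files, write_output_csv(wide, file.path(outdir, "report_permeation_table.csv")))
  }
  if (file.exists(nca_path)) {
    d <- read.csv(nca_path)
    rows <- c(t_half_h = "t_half_h", t_max_h = "t_max_h",
              c_max_ng_per_ml = "c_max_ng_per_ml",
              auc_0_t_ng_h_per_ml = "auc_0_t_ng_h_per_ml",
              auc_0_inf_ng_h_per_ml = "auc_0_inf_ng_h_per_ml",
              auc_ratio = "auc_ratio",
              aumc_0_inf_ng_h2_per_ml = "aumc_0_inf_ng_h2_per_ml",
              mrt_0_inf_h = "mrt_0_inf_h", lambda_z_per_h = "lambda_z_per_h")
    if (!all(rows %in% names(d))) {
      stop_input("nca_parameters.csv lacks the expected unit-labelled columns")
    }
    wide <- data.frame(parameter = names(rows), check.names = FALSE)
    for (i in seq_len(nrow(d))) {
      wide[[d$formulation[i]]] <- as.numeric(d[i, rows])
    }
    files <- c(files, write_output_csv(wide, file.path(outdir, "report_pk_table.csv")))
  }
  sections <- list()
  if (file.exists(fold_path)) {
    f <- read.csv(fold_path)
    sections$folds <- data.frame(section = "pk_fold_change",
                                 endpoint = f$parameter, group = f$test_formulation,
                                 reference = f$reference_formulation,
                                 direction = f$direction, value = f$fold)
  }
  if (file.exists(chg_path)) {
    g <- read.csv(chg_path)
    sections$changes <- data.frame(section = "efficacy_percent_change",
                                   endpoint = g$endpoint, group = g$group,
                                   reference = g$reference,
                                   direction = g$comparison, value = g$percent)
  }
  if (length(sections) > 0) {
    files <- c(files, write_output_csv(dplyr::bind_rows(sections),
                                       file.path(outdir, "report_changes.csv")))
  }
  files
}
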