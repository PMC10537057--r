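# Tidy CSV interchange: one reader/writer pair per experiment schema.
# All files are UTF-8, dot-decimal, header row mandatory; time is hours and
# units are fixed in the column names.

read_schema_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop_input(sprintf("input file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    stop_input(sprintf("%s: missing column(s) %s",
                       basename(path), paste(miss, collapse = ", ")))
  }
  num_cols <- grep("^(time_h|conc_|q_|value|dilution_factor)", names(d), value = TRUE)
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(vals) & !is.na(d[[col]]))
    if (length(bad) > 0) {
      stop_input(sprintf("%s: column `%s` is not numeric at row %d",
                         basename(path), col, bad[1]))
    }
    d[[col]] <- vals
  }
  tibble::as_tibble(d)
}

#' Read a release-experiment CSV
#'
#' Expected columns: `time_h`, `conc_ug_per_ml`, optional `dilution_factor`
#' (default 1). Experiment constants come from the arguments.
#'
#' @param path CSV path.
#' @param sample_volume,medium_volume,dose Constants of the experiment
#'   (mL, mL, µg); see [release_experiment()].
#' @return A [release_experiment()].
#' @export
read_release_csv <- function(path, sample_volume = 0, medium_volume = 50, dose) {
  d <- read_schema_csv(path, c("time_h", "conc_ug_per_ml"))
  df <- if ("dilution_factor" %in% names(d)) d$dilution_factor else 1
  release_experiment(d$time_h, d$conc_ug_per_ml, dilution_factors = df,
                     sample_volume = sample_volume,
                     medium_volume = medium_volume, dose = dose)
}

#' Read a cumulative-permeation CSV
#'
#' Expected columns: `time_h`, `q_ug_per_cm2`, optional `formulation`. A file
#' with several formulations yields one experiment per formulation.
#'
#' @param path CSV path.
#' @param c0,area Donor concentration (µg/mL) and corneal area (cm²).
#' @return A named list of [permeation_experiment()].
#' @export
read_permeation_csv <- function(path, c0 = 500, area = 0.636) {
  d <- read_schema_csv(path, c("time_h", "q_ug_per_cm2"))
  if (!"formulation" %in% names(d)) d$formulation <- "formulation"
  lapply(split(d, d$formulation), function(g) {
    g <- g[order(g$time_h), ]
    permeation_experiment(g$time_h, g$q_ug_per_cm2, c0 = c0, area = area,
                          label = g$formulation[1])
  })
}

#' Read an aqueous-humor concentration CSV
#'
#' Expected columns: `subject_id`, `formulation`, `time_h`, `conc_ng_per_ml`.
#'
#' @param path CSV path.
#' @return A tibble in the same long form.
#' @export
read_ah_csv <- function(path) {
  read_schema_csv(path, c("subject_id", "formulation", "time_h", "conc_ng_per_ml"))
}

#' Read an efficacy-panel CSV
#'
#' Expected columns: `group`, `endpoint`, `replicate`, `value`.
#'
#' @param path CSV path.
#' @return An [efficacy_panel()].
#' @export
read_efficacy_csv <- function(path) {
  efficacy_panel(read_schema_csv(path, c("group", "endpoint", "replicate", "value")))
}

write_output_csv <- function(d, path) {
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}
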