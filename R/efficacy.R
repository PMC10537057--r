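# Pharmacodynamic efficacy scoring: clinical-grade and marker summaries,
# percent change versus control groups, hemocytometer arithmetic, and
# supporting one-way ANOVA / t-test comparisons.

#' Construct an efficacy panel
#'
#' Long-form replicate records of the pharmacodynamic endpoints measured in
#' an ocular-inflammation efficacy study: clinical grade (0-4 scale),
#' aqueous-humor cell count (cells/mL), total protein (mg/mL), TNF-alpha,
#' IL-6 and MPO levels (pg/mL), and optional histology grade (0-4).
#'
#' @param data A data frame with columns `group`, `endpoint`, `replicate`,
#'   `value`. Endpoints must come from
#'   `clinical_score, cell_count, protein, TNFa, IL6, MPO, histo_score`;
#'   grade endpoints must lie in \[0, 4\] and all values must be nonnegative.
#' @return A tibble of class `efficacy_panel`.
#' @export
efficacy_panel <- function(data) {
  need <- c("group", "endpoint", "replicate", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_input(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(data$endpoint), EFFICACY_ENDPOINTS)
  if (length(bad) > 0) {
    stop_input(sprintf("unknown endpoint(s): %s", paste(bad, collapse = ", ")))
  }
  check_numeric(data$value, "value", min = 0)
  grades <- data$value[data$endpoint %in% c("clinical_score", "histo_score")]
  if (any(grades > 4)) {
    stop_input("grade endpoints must lie on the 0-4 scale")
  }
  structure(tibble::as_tibble(data[need]),
            class = c("efficacy_panel", class(tibble::tibble())))
}

#' Per-group, per-endpoint summary statistics
#'
#' Sample mean and standard deviation (n - 1 denominator; 0 when n = 1) with
#' the replicate count, for every group x endpoint present in the panel.
#'
#' @param panel An [efficacy_panel()].
#' @return A tibble: `group`, `endpoint`, `mean`, `sd`, `n`.
#' @examples
#' panel <- gen_efficacy_panel(efficacy_sim_params(seed = 1))
#' summarize_groups(panel)
#' @export
summarize_groups <- function(panel) {
  stopifnot(inherits(panel, "efficacy_panel"))
  if (nrow(panel) == 0) stop_input("panel is empty")
  panel |>
    dplyr::group_by(.data$group, .data$endpoint) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Percent reduction of a treated mean relative to a reference
#'
#' `(reference - treated) / reference x 100`, the convention for reporting
#' suppression of an inflammatory endpoint relative to the untreated disease
#' (LPS-control) group.
#'
#' @param reference_mean Reference (e.g. untreated uveitis) group mean, > 0.
#' @param treated_mean Treated group mean.
#' @return Percent reduction (positive when the treated mean is lower).
#' @examples
#' percent_reduction(45.61, 16.27)  # 64.3
#' @export
percent_reduction <- function(reference_mean, treated_mean) {
  check_numeric(reference_mean, "reference_mean")
  check_numeric(treated_mean, "treated_mean")
  if (any(reference_mean <= 0)) stop_input("`reference_mean` must be > 0")
  (reference_mean - treated_mean) / reference_mean * 100
}

#' Percent increase of an elevated mean over a control
#'
#' `(elevated - control) / control x 100`, the convention for reporting
#' disease-induced elevation over the healthy control group.
#'
#' @param control_mean Healthy-control group mean, > 0.
#' @param elevated_mean Elevated (disease) group mean.
#' @return Percent increase.
#' @examples
#' percent_increase(5.05, 45.61)  # 803.2
#' @export
percent_increase <- function(control_mean, elevated_mean) {
  check_numeric(control_mean, "control_mean")
  check_numeric(elevated_mean, "elevated_mean")
  if (any(control_mean <= 0)) stop_input("`control_mean` must be > 0")
  (elevated_mean - control_mean) / control_mean * 100
}

#' Aqueous-humor cell concentration from a hemocytometer count
#'
#' `count x dilution x conversion`. Defaults assume the 1:1 Turk's-stain mix
#' (dilution 2) and the standard improved-Neubauer chamber factor of 10^4
#' per mL.
#'
#' @param chamber_count Cells counted in the chamber, >= 0.
#' @param stain_dilution_factor Dilution applied during staining.
#' @param hemocytometer_conversion Chamber-to-mL conversion factor.
#' @return Cells per mL of aqueous humor.
#' @examples
#' cells_per_ml(50)  # 1e6
#' @export
cells_per_ml <- function(chamber_count, stain_dilution_factor = 2,
                         hemocytometer_conversion = 1e4) {
  check_numeric(chamber_count, "chamber_count", min = 0)
  check_numeric(stain_dilution_factor, "stain_dilution_factor", min = 0)
  check_numeric(hemocytometer_conversion, "hemocytometer_conversion", min = 0)
  chamber_count * stain_dilution_factor * hemocytometer_conversion
}

#' Group comparison for one endpoint
#'
#' One-way ANOVA across all groups plus pairwise two-sample t-tests of each
#' group against a named reference, flagged at p < 0.05. The default t-test
#' is unpaired Welch (separate animals per group); a paired option exists for
#' designs with matched eyes. Degenerate cases (zero within-group variance)
#' are reported with `NA` p-values rather than failing.
#'
#' @param panel An [efficacy_panel()].
#' @param endpoint One endpoint name present in the panel.
#' @param reference Reference group for the pairwise tests (default `"LIU"`,
#'   the untreated disease control).
#' @param paired Use paired t-tests.
#' @param p_adjust Multiplicity correction for the pairwise p-values, as in
#'   [stats::p.adjust()]; `"none"` by default.
#' @return A list of class `group_comparison`: `endpoint`, `anova`
#'   (`f_value`, `p_value`, `df`), and `pairwise` (tibble: `group`,
#'   `t_p_value`, `significant`).
#' @examples
#' panel <- gen_efficacy_panel(efficacy_sim_params(seed = 1))
#' compare_groups(panel, "protein")
#' @export
compare_groups <- function(panel, endpoint, reference = "LIU",
                           paired = FALSE, p_adjust = "none") {
  stopifnot(inherits(panel, "efficacy_panel"))
  d <- panel[panel$endpoint == endpoint, ]
  if (nrow(d) == 0) stop_input(sprintf("endpoint `%s` not in panel", endpoint))
  groups <- unique(d$group)
  if (length(groups) < 2) stop_input("need at least 2 groups to compare")
  if (min(table(d$group)) < 2) stop_input("need at least 2 replicates per group")
  if (!reference %in% groups) {
    stop_input(sprintf("reference group `%s` not in panel", reference))
  }
  if (stats::sd(d$value) == 0) {
    # every replicate identical: both mean squares vanish, F is undefined
    f_value <- NA_real_
    p_value <- NA_real_
    tab <- list(Df = c(length(groups) - 1L, nrow(d) - length(groups)))
  } else {
    fit <- aov(value ~ group, data = d)
    tab <- summary(fit)[[1]]
    f_value <- tab[["F value"]][1]
    p_value <- tab[["Pr(>F)"]][1]
    if (!is.finite(f_value)) f_value <- NA_real_
  }
  ref_values <- d$value[d$group == reference]
  others <- setdiff(groups, reference)
  p_pair <- vapply(others, function(g) {
    tryCatch(
      t.test(d$value[d$group == g], ref_values, paired = paired,
             var.equal = FALSE)$p.value,
      error = function(e) NA_real_
    )
  }, numeric(1))
  p_pair <- stats::p.adjust(p_pair, method = p_adjust)
  structure(
    list(
      endpoint = endpoint,
      reference = reference,
      anova = list(f_value = f_value,
                   p_value = if (is.finite(p_value %||% NA_real_)) p_value else NA_real_,
                   df = tab[["Df"]]),
      pairwise = tibble::tibble(
        group = others,
        t_p_value = unname(p_pair),
        significant = !is.na(p_pair) & p_pair < 0.05
      )
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> endpoint %s: ANOVA F = %s, p = %s\n",
              x$endpoint, fmt_num(x$anova$f_value), fmt_num(x$anova$p_value, 3)))
  cat(sprintf("  pairwise vs %s:\n", x$reference))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("    %-14s p = %-10s %s\n", x$pairwise$group[i],
                fmt_num(x$pairwise$t_p_value[i], 3),
                if (isTRUE(x$pairwise$significant[i])) "*" else ""))
  }
  invisible(x)
}
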