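---
title: "Methods: ocular release, permeation, pharmacokinetics and efficacy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular release, permeation, pharmacokinetics and efficacy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocukin)
```

# The problem

Topical ocular delivery of corticosteroids such as dexamethasone sodium
phosphate is limited by precorneal clearance and the tight junctions of the
corneal epithelium. Mucoadhesive chitosan nanoparticles, optionally coated
with hyaluronic acid, are a standard strategy to extend residence time and
transcorneal flux. Evaluating such a formulation produces four quantitative
data sets, each with its own small model:

1. **In vitro release** from dialysis bags into simulated tear fluid, with
   withdraw-and-replace sampling, summarised as cumulative percent released
   and a Higuchi square-root-of-time fit.
2. **Ex vivo transcorneal permeation** in Franz-type diffusion cells,
   summarised as steady-state flux, apparent permeability, lag time and
   enhancement ratio over the plain drug solution.
3. **Ocular pharmacokinetics** of aqueous-humor concentration–time
   profiles, summarised by non-compartmental analysis (NCA).
4. **Pharmacodynamic efficacy** in the endotoxin-induced uveitis rabbit
   model: clinical grades, cellular infiltration, protein and cytokine
   levels, reported as group means, percent changes and ANOVA comparisons.

`ocukin` implements all four analyses plus seeded generators that emulate
each experiment, so the entire pipeline can be exercised and validated with
no external data.

# Release kinetics

## Two estimators of cumulative percent released

With sampled supernatant concentration $C_n$ (µg/mL), dilution factor
$DF_n$, medium volume $V_m$ (mL) and dose $D$ (µg), the textbook estimator
is

$$\%DR_n = \frac{C_n \cdot DF_n \cdot V_m}{D} \times 100 .$$

Under a withdraw-and-replace protocol this ignores the drug mass carried out
in earlier aliquots, so it increasingly underestimates cumulative release.
The mass-conserving estimator adds that mass back:

$$A_n = C_n DF_n V_m + \sum_{i<n} C_i DF_i V_s, \qquad \%DR_n = A_n / D \times 100,$$

with $V_s$ the aliquot volume. Both are provided
(`percent_released_eq1()`, `percent_released_corrected()`); the corrected
form is the package default because it inverts the sampling process exactly
(the test suite verifies the inversion against the generator's internal mass
ledger to $10^{-6}$ relative and better). The uncorrected form is retained
because published release tables are frequently computed with it, and
comparability sometimes matters more than mass balance. The corrected value
is never smaller than the uncorrected one, with equality exactly when
$V_s = 0$ or all earlier concentrations are zero.

Percent released above 100 is flagged with a warning but not clipped:
assay noise can legitimately push an estimate past the nominal dose, and
silently truncating would bias the Higuchi fit.

## Higuchi fit

`fit_higuchi()` is ordinary least squares of percent released against
$\sqrt{t}$, reporting the slope $k_H$ (%·h$^{-1/2}$), intercept and $R^2$.
The intercept is free by default — a burst release shows up as a positive
intercept rather than contaminating the slope — and can be forced to zero.
With an intercept, $R^2$ is the usual centered coefficient of
determination; through the origin it is the uncentered one. Both live in
$[0, 1]$, and an exactly-flat curve with zero residuals is reported as
$R^2 = 1$ rather than `NaN`. At least three points with $t > 0$ are
required.

# Transcorneal permeation

The cumulative permeated amount per area $Q(t)$ (µg/cm²) of a
lag-then-linear permeation curve is fit by OLS over a steady-state window:
flux $J = dQ/dt$ (µg·cm$^{-2}$·h$^{-1}$), apparent permeability
$P_{app} = J/C_0$ (cm/h) with donor concentration $C_0$ (µg/mL), and lag
time $t_{lag} = -\,\text{intercept}/J$ for positive slopes.

The defining question is *which points are steady state*. When the user
does not supply a window, `steady_state_flux()` examines every contiguous
tail window of at least 4 points, computes the window's $R^2$, and takes
the window with the highest $R^2$, preferring the longer window on ties
(within $10^{-9}$). This reproduces the usual visual late-linear reading
while staying reproducible and overridable (`window = c(t_min, t_max)`).
Curves with only 3 points are fit whole. A negative fitted slope warns but
returns, since a mildly decreasing tail is data, not an error; identical
sampling times are a singular fit and do error.

The working time unit is hours throughout, matching the scale on which
corneal permeation parameters are conventionally reported; per-second
values are accepted through `convert_rate()`. The enhancement ratio is the
flux ratio of a test formulation over a reference; when per-replicate flux
vectors are supplied it can average per-replicate ratios instead of
dividing mean fluxes — the two differ slightly (ratio of means vs mean of
ratios), which is exactly why reported enhancement-ratio columns carry
standard deviations.

`cumulative_from_receptor_conc()` converts sampled receptor concentrations
to cumulative amounts with the same withdrawal correction as the release
module, divided by the exposed corneal area (defaults: 6.9 mL receptor,
0.636 cm² cross-section, 500 µg/mL donor).

# Non-compartmental pharmacokinetics

`run_nca()` composes four operations, each independently exported and
tested:

- **`cmax_tmax()`** — maximum observed concentration; ties resolve to the
  earliest time.
- **`auc_trapezoid()` / `aumc_trapezoid()`** — linear trapezoid on every
  interval by default. The log-down variant (`method = "linlog"`) uses the
  log trapezoid on strictly declining positive segments and is available but
  not default: the linear rule is the simplest widely published convention,
  and reproducibility across tools matters more here than the small bias
  difference. The first-moment integral stays linear in both modes.
- **`terminal_slope()`** — $\lambda_z$ from unweighted OLS on
  $\ln C$ vs $t$. Candidate sets are the last $k$ positive-concentration
  points strictly after $T_{max}$, $k = 3$ up to all post-peak points. The
  set maximising adjusted $R^2$ wins; any set within $10^{-4}$ of the best
  with more points is preferred (the convention of automatic terminal-phase
  selection in standard PK software). The slope must be negative, otherwise
  the terminal phase is undefined and a typed error is raised. No weighting
  is applied.
- **`extrapolate_inf()`** — $AUC_{0-\infty} = AUC_{0-t} + C_{last}/\lambda_z$,
  $AUMC_{0-\infty} = AUMC_{0-t} + C_{last} t_{last}/\lambda_z + C_{last}/\lambda_z^2$,
  and $MRT = AUMC_{0-\infty}/AUC_{0-\infty}$.

Concentrations below a profile's limit of quantification are dropped after
the last quantifiable sample and treated as missing before it, mirroring how
ocular profiles of fast-clearing solutions become undetectable after a few
hours.

Ocular aqueous-humor sampling is destructive, so a full profile per animal
rarely exists; `mean_profiles()` pools a tidy long table into one mean
profile per formulation, the default unit of analysis. Per-subject NCA is
available for designs with complete profiles.

`fold_change()` encodes the narrative convention of PK comparisons:
"x-fold greater" is test/reference, "x-fold lower" is reference/test.

## Accuracy expectations

On a Bateman curve ($C(t) = A(e^{-k_e t} - e^{-k_a t})$,
$A = \frac{F D}{V}\frac{k_a}{k_a - k_e}$) sampled at 0.01 h over
48 h (about seven terminal half-lives at $k_e = 0.1$/h), the pipeline's
$AUC_{0-\infty}$, $t_{1/2}$, MRT and $T_{max}$ agree with the closed forms
to well under 0.5%. The residual deviation is structural, not numerical:
automatic $\lambda_z$ selection admits points where absorption still
contributes a vanishing amount of curvature. The acceptance suite fixes
this problem size; the parameter-recovery study uses 500 replicates of an
8-point sparse ocular schedule (0.5–24 h) at 10% lognormal noise and
requires the median recovered half-life within 10% of $\ln 2 / k_e$.

# Efficacy scoring

`summarize_groups()` gives mean, SD ($n-1$; 0 when $n = 1$) and $n$ per
group × endpoint. Percent changes are directional by design:
`percent_reduction(reference, treated)` against the untreated disease
(LPS-control) group, `percent_increase(control, elevated)` against the
healthy control group — the two conventions used when reporting suppression
and induction of inflammatory endpoints. They are exact inverses: an
$x$% increase is undone by a $100x/(100+x)$% reduction.
`cells_per_ml()` performs the hemocytometer arithmetic
(count × stain dilution × chamber factor; defaults 2 and $10^4$, both
configurable since chamber conventions vary).

`compare_groups()` runs a one-way ANOVA across groups and pairwise
two-sample t-tests against a named reference, flagged at $p < 0.05$. The
default t-test is unpaired Welch: treatment groups contain different
animals, so a paired test would be a design error (a paired option exists
for matched-eye designs). No multiplicity correction is applied by default
— pairwise contrasts against a single control are reported raw, as is usual
in this literature — but `p_adjust` accepts any `stats::p.adjust` method.
Zero-variance groups yield `NA` statistics rather than failures.

# The synthetic generators

Each generator draws from its own seeded RNG stream (`withr::with_seed`),
leaving the global RNG untouched; identical parameters give bit-identical
output.

- **Aqueous humor**: Bateman curves with multiplicative lognormal noise
  (unit mean, chosen CV). Lognormal keeps concentrations positive, the
  natural choice for assay noise on strictly positive measurements.
- **Release**: truth is $f(t) = \min(1,\, burst + (k_H/100)\sqrt{t})$; the
  measurement process is simulated event by event — released drug mixes
  instantly into the medium (well-mixed assumption), the aliquot is removed
  at the sampling instant, then replaced with drug-free medium. The
  generator returns its internal truth and a full mass ledger so estimators
  can be validated against it; the ledger conserves mass to $10^{-9}$
  relative at every event.
- **Permeation**: $Q(t) = \max(0, J(t - t_{lag}))$ plus additive Gaussian
  noise, monotonicity restored by cumulative maximum (a cumulative amount
  cannot decrease).
- **Efficacy**: Normal draws per group × endpoint, clipped to $[0, 4]$ for
  grade endpoints and to nonnegative values elsewhere. Clipping (rather
  than rejection sampling) slightly shifts extreme-mean draws; with the
  default means and small SDs the effect is negligible.

Default parameters are the study conditions of the motivating experiment
type: 50 mL simulated tear fluid, 1 mL aliquots, 1000 µg dose, 12 h release
with $k_H \approx 22$%·h$^{-1/2}$; fluxes of roughly 1.8, 8.3 and
17.8 µg·cm$^{-2}$·h$^{-1}$ for solution, uncoated and coated nanoparticles;
Bateman profiles whose half-lives (2.18, 5.44, 7.34 h) and peak
concentrations match the published parameter table of the three
formulations; and a five-group efficacy panel with $n = 3$ whose clinical
score and protein means are the published group summaries (cytokine and
cell-count levels are illustrative, consistent with the published percent
reductions, since those group means are only published graphically).

What the generators deliberately do **not** emulate: mechanistic
diffusion/erosion of the chitosan matrix, corneal-tissue compartments or
active transport, between-animal variance components, correlated
measurement error, and sub-integer grade aggregation. Passing tests
therefore demonstrate that the estimators invert the *assumed* measurement
models; they cannot certify behaviour on real data that violates those
assumptions (for example Fickian release that only approximates
$\sqrt{t}$, or heteroscedastic assays).

# Pipeline and numerical choices

`run_pipeline()` executes simulate → release → permeation → nca → efficacy
→ report from a validated YAML configuration (unknown keys rejected;
constants checked positive; input paths checked before any stage runs).
All interchange is tidy CSV with units embedded in column names
(`flux_j_ug_per_cm2_per_h`, `auc_0_inf_ng_h_per_ml`, ...); the report stage
refuses to assemble files whose unit-labelled columns are missing. Every run
writes a manifest (version, config hash, seed, timestamps, per-stage file
list) and a stage-level log echoing parameters, so each reported number is
traceable to its configuration. Re-running an identical configuration
reproduces byte-identical numeric outputs.

Other numerical conventions, collected: ties in $C_{max}$ go to the
earliest time; flux-window ties go to the longer window; $\lambda_z$
candidate ties (within $10^{-4}$ adjusted $R^2$) go to more points;
$R^2$ of a zero-variance response with zero residuals is 1; fold changes
and enhancement ratios require strictly positive denominators and raise
typed errors otherwise.

# Known limitations

- The Bateman generator excludes the coincident-rate limit
  $k_a = k_e$ (the $t\,e^{-kt}$ form); profiles near that regime should be
  simulated with distinct rates.
- NCA on mean profiles understates between-animal variability; SDs of NCA
  parameters require per-subject profiles, which destructive ocular
  sampling rarely provides.
- The release model is square-root-of-time with an optional burst; other
  release laws (first-order, Korsmeyer–Peppas, Weibull) are out of scope.
- Enhancement ratios and fold changes computed from group means differ
  slightly from means of per-replicate ratios; both conventions are
  supported where replicate data exist, and the difference (below 1% in
  the bundled reference tables) is documented rather than hidden.
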