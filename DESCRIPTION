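Package: ocukin
Title: Ocular Nanoparticle Pharmacokinetics, Release and Efficacy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for topical ocular nanoparticle
    drug-delivery studies. Computes cumulative percent drug release from
    dialysis-bag sampling records (with and without correction for aliquot
    withdrawal and medium replacement) and fits the Higuchi square-root-of-time
    model; estimates steady-state transcorneal flux, apparent permeability,
    lag time and enhancement ratios from Franz-cell cumulative-permeation
    curves; performs non-compartmental pharmacokinetic analysis (Cmax, Tmax,
    terminal slope, half-life, AUC, AUMC, MRT, extrapolation to infinity) of
    aqueous-humor concentration-time profiles; and aggregates pharmacodynamic
    efficacy endpoints (clinical grades, cell counts, protein and cytokine
    levels) into group summaries, percent changes and ANOVA comparisons.
    A seeded synthetic-data generator emulates each experiment (Bateman
    absorption-elimination profiles, square-root release with withdrawal
    bookkeeping, lag-then-linear permeation, group-structured endpoints) so
    the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
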