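Package: boutondyn
Title: Longitudinal Quantification of Axonal Bouton Dynamics in Two-Photon Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, detection, tracking and statistical analysis of
    axonal bouton dynamics in longitudinal in vivo two-photon imaging
    experiments. Generates synthetic GFP-labelled axons with stochastic
    en passant (EPB) and terminaux (TB) bouton gain/loss dynamics across
    imaging sessions, renders them as noisy 3D image stacks, detects
    boutons by intensity-ratio and protrusion-length criteria, tracks
    bouton identities across sessions with hysteresis presence rules,
    computes density/turnover/gain/loss statistics, and runs the
    rank-based inference battery (Mann-Whitney U with mean ranks and
    eta-squared, Wilcoxon signed-rank, Friedman, sphericity-corrected
    mixed ANOVA, Bonferroni adjustment). Includes an encoding of the
    intermittent theta-burst stimulation (iTBS) pulse schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
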