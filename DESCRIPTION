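Package: spindledyn
Title: Quantification of Mitotic Spindle, EB1 Comet and Tubulin
    Polymerisation Dynamics in Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-validated toolkit for quantifying
    mitotic spindle assembly in syncytial Drosophila embryos and related
    in vitro assays. Detects and tracks spindle poles in fluorescence
    time-lapse movies and compares centrosome-to-centrosome distances;
    builds per-spindle and composite kymographs along the pole-pole axis
    and extracts Otsu-threshold microtubule growth-profile contours with
    front-speed and flatness statistics; measures nuclear-envelope-breakdown
    (NEB)-aligned nuclear/spindle fluorescence dynamics with photobleaching
    correction; filters affinity-purification mass-spectrometry tables
    against a negative-control (false-positive) database with bait-relative
    abundance restriction and two-run reproducibility reports; and
    characterises tubulin polymerisation curves by a four-parameter
    logistic fit. A synthetic-data module generates embryo movies, AP-MS
    tables and polymerisation curves with exported ground truth so every
    stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
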