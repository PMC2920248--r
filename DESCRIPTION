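Package: volvoxsteer
Title: Agent-Based Simulation and Trajectory Analysis of Phototactic
    Steering in Volvox Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic, cell-resolved model of phototactic steering in
    large Volvox spheroids of the section Volvox (e.g. Volvox rousseletii).
    Builds polarized spheroids with an anterior-posterior eyespot and
    cell-spacing gradient, models per-cell light perception through a
    piecewise eye directivity, drives a per-cell flagellar beating-mode
    state machine (normal versus transiently reversed ciliary beating),
    and integrates overdamped rigid-body locomotion with bottom-heavy
    gravitaxis.  Includes virtual photoaccumulation and dark-light switch
    assays in observation chambers, a rotating-filter pulse-train
    stimulus, a synthetic trajectory generator with known ground truth,
    and the trajectory quantification pipeline (photoaccumulation index,
    sector-wise speed profiles, sinking depth, pulse-response lag).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
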