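Package: ivgpr
Title: In Vitro Gas Production Kinetics, Methane Yield, and Repeatability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the in vitro gas production technique
    (IVGPT) used to screen ruminant feeds: reads per-bottle cumulative
    gauge-pressure logs from closed-bottle fermentation systems, applies
    two-phase blank (baseline) correction, converts pressure to cumulative
    gas volume at standard temperature and pressure per gram of incubated
    dry matter via the ideal gas law, extracts nonparametric kinetic curve
    parameters (total gas production at chosen hours, half-maximum volume
    and time, maximum rate and its time), predicts methane concentration
    and yield from gas-chromatography standard curves, computes baseline-
    corrected dry-matter degradation, and summarises repeatability across
    fermentation trials and rumen-fluid donor types as coefficients of
    variation with a fixed-effects trial-by-donor model and Welch tests.
    Includes a seeded synthetic-trial generator with known ground truth so
    the whole pipeline runs without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
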