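Package: kneegap
Title: Virtual Gap-Balance Simulation for Mechanically Aligned Total Knee Arthroplasty
Version: 0.1.0
Authors@R:
    person("kneegap", "developers", email = "kneegap@example.org", role = c("aut", "cre"))
Description: Simulates measured-resection, mechanically aligned total knee
    arthroplasty on three-dimensional knee surface models. Builds femoral and
    tibial mechanical axes and an anatomical coordinate frame from landmarks,
    constructs the four standard posterior femoral reference axes (surgical
    transepicondylar axis, Whiteside's line, posterior condylar axis with 3
    degrees of external rotation, and the flexion-extension axis from
    best-fitted sagittal condylar circles), performs virtual 9 mm bone cuts,
    and computes per-compartment extension and flexion gap distances,
    medio-lateral imbalance and flexion-extension imbalance. Includes a
    parametric synthetic knee cohort generator with analytic ground truth for
    varus and valgus osteoarthritic populations, cohort statistics (Welch
    t-test, ANOVA with Tukey post hoc, chi-squared, balance-rate tables), and
    command-line entry points for generation, simulation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
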