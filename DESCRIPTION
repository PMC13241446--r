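Package: tauavrami
Title: Biomechanics-Informed Avrami Kinetics of Post-Traumatic Tau Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic Kolmogorov-Johnson-Mehl-Avrami (KJMA)
    nucleation-growth kinetics for the progression of phosphorylated-tau
    burden after traumatic brain injury. Provides the closed-form extended
    volume with a quadrature fallback near parameter degeneracies, a
    saturation-bounded transformed percentage, two-stage calibration
    (seeded random search plus Nelder-Mead refinement) against AT8
    histology time series, one-factor-at-a-time sensitivity scans,
    projection of the homogeneous curve onto nodal mechanical-strain
    fields through a fourth-power weighting with an exact mean-enforcing
    correction factor, an element-removal atrophy surrogate, synthetic
    strain-field generators, CSV and VTK unstructured-grid input/output,
    and a command-line workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
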