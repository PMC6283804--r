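Package: redosim
Title: Hybrid Planar/SPECT Image-Based Dosimetry for Re-188 Lipiodol
    Radioembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-level internal dosimetry for Re-188 Lipiodol
    radioembolization from serial anterior/posterior whole-body planar
    images and a single quantitative SPECT study. Implements conjugate-view
    (geometric-mean) relative time-activity curves with threshold ROIs,
    paralyzable dead-time correction and rigid planar registration;
    volume-matched tumor segmentation and organ activity quantification on
    SPECT; weighted mono-exponential pharmacokinetic fitting with
    effective/biological half-life conversion; piecewise-analytic
    time-integrated activity coefficients (residence times); mass-scaled
    organ and sphere-model S-factor dose calculation; and a
    scan-protocol sparsification study (time-point subsets and
    single-scan protocols) with rank-sum tests and box-plot summaries.
    Includes a synthetic patient-cohort generator (digital phantom,
    planar projections, SPECT volumes, Poisson counting and dead-time
    models) so the whole pipeline is testable without patient data.
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
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readr,
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
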