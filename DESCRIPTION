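Package: octinflate
Title: Corneal Inflation Elastography from Line-Field OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for optical coherence tomography (OCT)
    corneal inflation testing. Simulates ground-truth corneal geometry over
    a pressure and hydration schedule, renders synthetic line-field OCT
    B-scans with speckle and a finite axial point-spread function, segments
    anterior and posterior corneal boundaries, corrects optical path lengths
    by the tissue group refractive index, and derives the biomechanical
    measurands of an inflation test: apex thickness, anterior radius of
    curvature, apex displacement, thin-walled-sphere stress, volumetric
    strain, tangent elastic modulus, loading/unloading hysteresis, and
    hydration-time effects with exact Wilcoxon signed-rank testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
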