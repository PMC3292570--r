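Package: dtemu
Title: Device Thrombogenicity Emulation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lagrangian post-processing of platelet stress-loading histories
    for rotary blood pumps and other blood-contacting devices. Computes
    scalar stress and stress accumulation (SA, Pa.s) along platelet
    trajectories from viscous and turbulent (Reynolds) stress tensors,
    collapses trajectory ensembles into bootstrapped "thrombogenic
    footprint" probability density functions, restricts analyses to
    cylindrical regions of interest, extracts hot-spot stress waveforms and
    translates them into cone-plate shearing-device speed schedules, and
    fits and compares Platelet Activation Rates (PAR) from Platelet
    Activity State assay time series. Includes analytic flow fields and
    seeded synthetic-data generators so the full pipeline runs without any
    proprietary CFD input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    utils,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
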