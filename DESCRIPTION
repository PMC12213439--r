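Package: oscillometry
Title: Analytical Models and Simulation of Oscillometric Blood Pressure
    Oscillograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical models of the oscillometric height and area
    oscillograms built on a sigmoidal arterial blood volume-transmural
    pressure relationship, together with a forward simulator of cuff-pressure
    recordings (elastic, Hammerstein and Wiener viscoelastic variants,
    constant or pressure-dependent volume-to-pressure scaling, and a Boyle's
    law cuff-arm model), an automated oscillogram-construction algorithm
    (band-pass oscillation extraction, pulse detection and gating, per-pulse
    shape features, smoothing, tail trimming and normalization), and a
    constrained nonlinear least-squares framework for fitting the models to
    measured oscillograms and evaluating modeling assumptions on synthetic
    recordings.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
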