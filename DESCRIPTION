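Package: circaluna
Title: Lunar Cycles and Circalunar Entrainment Analysis of Menstrual Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for synchronization between menstrual cycles
    and the three lunar months (synodic, anomalistic, tropical). Computes
    dated lunar event series (full/new moons, perigees/apogees, monthly
    declination standstills and 18.61-year standstill epochs) from a
    self-contained truncated lunar theory at whole-hour resolution; maps
    menses onsets to circular phases with axial duplication and runs
    Rayleigh and directed V tests; segments records into consistent-period
    episodes, estimates free-running periods by Lomb-Scargle periodogram,
    detects entrained runs of at least four consecutive cycles and builds
    limits-of-entrainment curves; simulates cohorts from a stochastic
    circle-map circalunar oscillator with ground-truth entrainment labels;
    and renders mensograms and annotated polar phase plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    tibble,
    stats,
    utils,
    grDevices
Suggests:
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
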