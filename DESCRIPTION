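Package: phoskit
Title: Carbon Uptake and Oxygen Evolution from pH-Oscillation and
    Membrane-Inlet Mass Spectrometry Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data reduction for light/dark-stepped microalgal incubations
    monitored by a high-resolution pH electrode (pH oscillation) and a
    membrane-inlet mass spectrometer. Converts pH and oxygen/argon time
    series into dissolved-inorganic-carbon uptake and oxygen evolution
    rates via a total-scale seawater carbonate-system engine, fits
    photosynthesis-irradiance curves with a dark-respiration offset,
    integrates chlorophyll-specific spectral absorption against lamp
    irradiance to obtain quantum yields of carbon and oxygen, and provides
    Gran titration alkalinity, electrode and oxygen calibration, detection
    limit statistics, perturbation sensitivity analysis, and a forward
    simulator that generates synthetic traces, spectra and titrations from
    known ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
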