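Package: aposignal
Title: Predator-Vision Color Metrics, Toxin Quantification, and Honest-Signal
    Analysis for Aposematic Wing Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studies of quantitative honesty
    in aposematic coloration, built around the red-and-black wing patterns of
    burnet moths and their cyanogenic glucoside defences. Provides a synthetic
    data generator (reflectance spectra, calibrated multispectral camera
    patches, specimen cohorts under configurable color-toxin scenarios, and
    LC-MS chromatograms), camera linearization and grey-standard
    normalization, polynomial mapping of camera channels to avian cone
    catches, tetrahedral-colorspace saturation and hue metrics,
    receptor-noise-limited chromatic and luminance contrasts in just
    noticeable differences, internal-standard LC-MS quantification of
    linamarin and lotaustralin, and the regression framework relating
    coloration to defence levels within and among populations, including
    stepwise multiple regression with collinearity and influence diagnostics,
    sex-by-population models with Tukey post-hoc tests, and linear mixed
    models for conspicuousness against natural plant backgrounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    withr,
    jsonlite,
    car,
    lme4,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
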