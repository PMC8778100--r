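Package: cacaoharvest
Title: Thermal-Time Crop Model for Cacao Harvest Date and Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A daily-step, thermal-time-driven simulator of cacao pod
    development for Colombian growing regions.  From a flowering date and a
    daily weather series the model accumulates growing degree-days above a
    10 C base temperature, predicts the pod maturation (harvest) day as the
    first day the regional thermal-time requirement (Tsum) is met, and
    simulates above-ground biomass with a radiation-use-efficiency (RUE)
    scheme driven by intercepted shortwave radiation through a logistic
    canopy growth/senescence pair.  Yield is the harvest-index fraction of
    accumulated biomass.  The package also provides regional Tsum
    characterisation from flowering-date samples, grid-search RUE
    calibration against observed yields, relative root-mean-square error
    (RRMSE) evaluation, a NASA-POWER-dialect weather reader, and a seeded
    synthetic weather generator emulating five Colombian regional climates
    so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
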