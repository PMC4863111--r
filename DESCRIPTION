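Package: glucolag
Title: Compartmental Modeling of Blood and Interstitial Fluid Glucose Kinetics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates glucose exchange between the blood and the interstitial
    fluid (ISF) through a compartmental microcirculation model: concentration
    gradient-driven transcapillary transport (Fick), pressure gradient-driven
    filtration and absorption with mixing (Starling-Landis), and semi-infinite
    diffusion within tissue solved with the error function (quasi-static) or by
    Duhamel superposition, with an independent finite-difference oracle. Includes
    estimation of the ISF lag time and grid fitting of the effective diffusion
    distance against measured ISF series, and synthetic-data generators emulating
    glucose-tolerance-test blood profiles, fluorescent-sensor readouts and
    isotope-tracer readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
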