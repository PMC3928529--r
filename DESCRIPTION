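Package: nlakes
Title: Empirical Nitrogen Critical Loads for High-Elevation Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring an empirical critical load of atmospheric
    nitrogen deposition for high-elevation lakes from paleolimnological and
    monitoring data. Implements bulk-deposition flux estimation from
    ion-exchange-resin collectors, censored-nutrient DIN/TP limitation
    classification, constant-rate-of-supply (CRS) lead-210 sediment
    geochronology with Monte-Carlo uncertainty and cesium-137 validation,
    diatom indicator-shift detection in dated stratigraphies, and exponential
    hindcasting of elevation-corrected wet nitrogen deposition to the detected
    shift window. Includes seeded synthetic-data generators for every input
    table so each stage has a parameter-recovery test with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
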