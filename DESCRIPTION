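Package: thermokin
Title: Thermal Degradation Kinetics of Anthocyanins and Antioxidant Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for isothermal degradation kinetics of
    anthocyanin pigments and antioxidant activity in plant extracts.
    Converts raw spectrophotometric readings into total monomeric
    anthocyanin content (pH-differential method) and Trolox-equivalent
    antioxidant activity (DPPH calibration), fits first-order degradation
    models per holding temperature, derives the thermal-resistance
    parameter set (rate constant k, decimal reduction time D, half-life,
    z-value, Arrhenius activation energy) with standard errors, and
    analyses sequential gastric-intestinal in vitro digestion time
    courses. A synthetic-data generator with known ground truth makes the
    whole chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
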