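Package: acitherm
Title: Photosynthetic Capacity and Thermal Acclimation from A/Ci Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates apparent maximum Rubisco carboxylation rate (Vcmax) and
    maximum electron transport rate (Jmax) from CO2-response (A/Ci) curves with
    the Farquhar-von Caemmerer-Berry model, fits their short-term temperature
    responses with a peaked Arrhenius function and the thermal response of net
    photosynthesis with a quadratic, and tests growth-CO2 by growth-temperature
    treatment effects with repeated-measures linear mixed models, AICc-based
    fixed-effect selection and Tukey post-hoc comparisons. Includes a synthetic
    climate-manipulation study generator with known ground truth so the full
    pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    nlme,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
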