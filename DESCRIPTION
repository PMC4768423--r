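Package: tumorgrowth
Title: Comparative Analysis of ODE Tumor Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines the seven classical ordinary-differential-equation models of
    tumor volume growth (exponential, Mendelsohn, logistic, linear, surface,
    Gompertz, Bertalanffy), their closed-form clinical predictions (maximum tumor
    size, doubling time, growth condition, and the minimum constant chemotherapy
    concentration needed for suppression), least-squares fitting with
    small-sample-corrected AIC model selection, and a truncated-fit/extrapolation
    experiment that quantifies how the choice of growth model changes clinically
    relevant predictions. Includes a synthetic xenograft-like data generator so
    the full workflow is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
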