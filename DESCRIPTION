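Package: soledrift
Title: Otolith-Based Ageing and Biophysical Dispersal Modelling of Juvenile Sole
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing the early life history of juvenile
    common sole (Solea solea) from otolith daily growth increments and for
    confronting those observations with a stage-structured Lagrangian
    individual-based model of egg and larval dispersal. Provides otolith
    ageing and calendar back-calculation of hatching and settlement dates,
    weekly arrival-distribution estimation, a four-stage (egg, yolk-sac,
    first-feeding, metamorphosing) particle-tracking simulator with
    temperature-dependent development and mortality, diel and tidally
    synchronised vertical migration, Visser-corrected vertical random
    walks on a pluggable flow-field interface, observed-versus-predicted
    arrival-curve comparison statistics, and seed-deterministic synthetic
    data generators for both sides of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
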