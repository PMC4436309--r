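Package: skullgeom
Title: Statistical Shape Modelling of the Growing Pediatric Skull
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based statistical geometry model of the skull for
    children 0-36 months old. Converts raw suture-pair landmark data to a
    homologous 60-landmark representation with suture widths and skull
    thickness, rigidly aligns subjects into an anatomical frame, fits
    per-block principal component analyses with a principal-component
    regression on age and head-circumference offset, predicts skull
    size/shape, suture widths and thickness fields, reconstructs continuous
    surfaces by radial basis function morphing, and tests predictors of
    suture width and skull thickness with a random-intercept linear mixed
    model using containment denominator degrees of freedom. Includes a
    synthetic cohort generator emulating age-dependent cranial growth,
    location-dependent suture closure and thickness distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    car,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
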