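Package: jointRT
Title: Joint Modelling of Item Responses and Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits joint latent-variable models for scored item responses and
    time-on-task data from computer-based assessments. Response accuracy
    follows a graded response model; log response times follow a one-factor
    lognormal model, optionally extended with cross-loadings of proficiency
    on individual item times. Marginal maximum likelihood estimation on a
    bivariate normal latent space, a two-step international/group calibration
    scheme, a measurement-invariance ladder with BIC selection, expected a
    posteriori scoring with EAP reliability, factor rotation of the
    cross-loading model, limited-information fit statistics for the graded
    response model, and a synthetic multi-group data generator emulating the
    PISA 2012 computer-based mathematics log-file structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
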