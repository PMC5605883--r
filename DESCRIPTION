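Package: codburden
Title: Cause-of-Death Estimation, Envelope Correction, and Premature-Mortality Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a vital-registration cause-of-death
    estimation chain: synthetic death-record generation with an SDI-driven
    epidemiological transition, data-quality star rating from completeness,
    garbage coding, and cause detail, garbage-code redistribution and
    completeness correction, ensemble cause-of-death modelling weighted by
    out-of-sample predictive validity, rescaling of cause-specific draws to an
    all-cause envelope, years-of-life-lost and age-standardised burden with
    draw-based uncertainty, and Gaussian-process expected burden as a function
    of the Socio-demographic Index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    MASS,
    lme4,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
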