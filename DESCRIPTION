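Package: qcindex
Title: Quality of Care Index Construction from Burden-of-Disease Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a 0-100 quality of care index (QCI) for a disease from
    long-format burden-of-disease measure tables (incidence, deaths,
    prevalence, YLL, YLD, DALY rates per 100,000). Four secondary ratios
    (mortality-to-incidence, prevalence-to-incidence, DALY-to-prevalence,
    YLL-to-YLD) are combined via the first principal component, oriented so
    that higher scores mean better care, and rescaled to 0-100. Also computes
    the gender disparity ratio (female QCI divided by male QCI), assigns
    socio-demographic index (SDI) quintiles, provides direct age
    standardization, and ships a synthetic data generator driven by a latent
    quality-of-care variable so the whole pipeline can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
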