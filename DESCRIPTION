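Package: diazofix
Title: Marine Dinitrogen Fixation Rates from 15N2 Tracer Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and scaling of marine biological dinitrogen (N2)
    fixation rates from 15N2 stable-isotope tracer experiments. Implements
    the isotope mass balance for bulk-community rates from particulate
    nitrogen enrichment (with detection limits and minimum quantifiable
    rates), single-cell rates for UCYN-A/haptophyte symbioses from nanoSIMS
    atom percent measurements and biovolume-derived nitrogen quotas
    (including the isotope-dilution correction), scaling of per-cell rates
    to volumetric rates via nifH gene-copy abundances with LOD/LOQ
    censoring, derived hydrochemical quantities (excess phosphate P*,
    mixed-layer depth, depth-integrated areal rates, Redfield carbon
    equivalents) and a nonparametric association screen. A seeded
    synthetic-survey generator emulates the statistical structure of a
    cruise dataset (correlated lognormal abundances, IRMS and ion-count
    noise) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
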