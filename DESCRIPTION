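Package: plever
Title: Analytical and Simulation Tools for Protein Leverage in Population Intake Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory-driven tools for detecting protein leverage -- the
    regulation of absolute protein intake that drives over-consumption of
    non-protein energy on protein-dilute diets -- in population dietary
    data.  Implements the exact density of the proportion of energy from
    protein when protein and non-protein intakes are bivariate normal
    (a ratio of correlated normals, via Kummer's confluent hypergeometric
    function), the expected leverage coefficient under a no-leverage null,
    a forward generative model linking true leverage strength to the
    index-of-dispersion ratio of intakes, seedable cohort simulators
    (bivariate normal, bivariate lognormal, leverage-generative), the
    log-log and power-law leverage estimators with covariate adjustment,
    and dispersion and coefficient-of-variation-ratio diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    MASS,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
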