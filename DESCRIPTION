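Package: pHsol
Title: pH-Dependent Solubility and Aggregation Propensity of Intrinsically
    Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts how the solubility (inverse aggregation propensity) of an
    intrinsically disordered protein changes with solution pH. Combines a
    pH-dependent per-residue lipophilicity scale (Henderson-Hasselbalch mixing
    of neutral- and charged-species values), fractional net charge and
    isoelectric point calculations under a configurable pKa set, sliding-window
    lipophilicity profiles, and an empirical bivariate polynomial solubility
    model that is linear in lipophilicity and quadratic in absolute net charge.
    Includes non-linear least-squares re-parameterization of the model from
    experimental solubility data, ordinary least-squares validation statistics,
    and a seeded generator of charge-flipped synthetic IDP variants with noisy
    solubility measurements for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
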