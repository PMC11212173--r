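Package: mcpaccess
Title: Multilevel Modelling and Travel-Time Accessibility Analysis of Modern
    Contraceptive Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing modern-contraceptive utilization from
    DHS-style women's survey records: variable recoding (method
    classification, media-exposure composite, education and wealth
    collapsing, district-level community aggregates), descriptive
    cross-tabulations with Pearson chi-square screening and VIF
    multicollinearity checks, a random-intercept binary logistic model fit
    by adaptive Gauss-Hermite quadrature with intraclass correlation and
    average marginal effects, road-network travel-time accessibility with
    class-specific speeds, lake barriers and facility snapping, and Jenks
    natural-breaks district classification. Includes a synthetic-data
    generator emulating the two-stage cluster structure of such surveys and
    a planar toy geography, so the whole pipeline runs end to end without
    restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
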