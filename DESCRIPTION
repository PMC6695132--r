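Package: pelagibm
Title: Full Life Cycle Individual-Based Model for Anchovy and Sardine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A one-dimensional, full life cycle, super-individual model of
    co-occurring European anchovy (Engraulis encrasicolus) and European
    sardine (Sardina pilchardus) populations in a temperate shelf sea.
    Growth follows a Wisconsin-type bioenergetics budget (consumption,
    respiration, egestion, excretion, specific dynamic action) with diel
    vertical migration between surface and sub-thermocline layers; egg
    production follows a capital-income energy allocation algorithm with a
    reproductive buffer, species-specific sea-surface-temperature spawning
    gates and an atresia rule; populations are two-way coupled to a
    synthetic water-column plankton climatology through grazing.  Includes
    genetic-algorithm calibration of half-saturation coefficients against
    size-at-age references, bisection calibration of juvenile natural
    mortality against reference biomasses, and a management-scenario engine
    for exploitation-rate sweeps and fishing-closure timing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
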