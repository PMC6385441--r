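Package: irontraffic
Title: Multi-Tier Kinetic Modeling of Iron Import and Trafficking in Growing Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental ordinary-differential-equation models of nutrient iron
    import, trafficking, and regulation in exponentially growing Saccharomyces
    cerevisiae (wild type and the Mrs3/4 double-deletion strain). Implements the
    one-, three-, four-, and nine-component model tiers with growth-dilution
    terms, expanding-steady-state solving with stiff integration and Newton
    polishing, Moessbauer spectral-group bookkeeping that converts measured iron
    pools into model components and data-based fluxes, a normalized-error
    coordinate-descent optimizer with tiered parameter transfer, one-at-a-time
    sensitivity analysis, in-silico nutrient sweeps and oxygen/nanoparticle
    phenotype experiments, and a synthetic-observation generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
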