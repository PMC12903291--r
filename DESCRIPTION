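Package: cmpflux
Title: Plasma Metabolome Chemometrics and Central Metabolic Pathway Flux Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential plasma-metabolite discovery by OPLS-DA with VIP
    scoring and permutation validation, two-group comparison of quantified
    plasma metabolite panels, and stoichiometric inference of relative
    metabolic fluxes over a ten-reaction central-metabolic-pathway network
    under pseudo-steady-state mass balances, normalized to glucose uptake
    (r1 = 100). Includes a seeded synthetic-data module that generates
    intensity matrices with planted differential metabolites, concentration
    panels, and flux scenarios with known ground truth, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
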