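Package: cbflux
Title: Constraint-Based Flux Analysis of Caldicellulosiruptor bescii Core Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling toolkit built around a fully
    specified core-metabolism network of the cellulolytic extreme thermophile
    Caldicellulosiruptor bescii. Implements flux balance analysis (FBA), flux
    variability analysis (FVA) and minimization of metabolic adjustment (MOMA)
    on stoichiometric models read from a YAML model dialect or tabular sheets;
    model quality checks (stoichiometric consistency, formula and charge
    balance, metabolite connectivity); randomized minimal-network essentiality
    classification with convergence diagnostics; and combinatorial strain
    design evaluation (knock-in catalog, design matrices, production
    envelopes) for ethanol yield optimization under electron-bifurcation
    redox constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
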