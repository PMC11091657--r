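Package: fluxgaba
Title: Constraint-Based Flux Inference for GABA-Producing Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers intracellular metabolic flux distributions of a
    GABA-producing Escherichia coli knockout strain from batch fermentation
    data.  Builds and validates stoichiometric metabolic models (BiGG-style
    JSON and SBML/FBC), simulates gene and reaction knockouts through
    gene-protein-reaction rules, converts fermentation time courses into
    specific growth and exchange rates over an automatically selected
    exponential-growth window, reconciles measured rates with the model by
    least-absolute-deviation fitting and parsimonious flux balance analysis,
    and classifies per-reaction flux changes between culture conditions.
    Ships a hand-curated central-carbon toy network and a synthetic
    fermentation-profile generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    yaml,
    Matrix,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
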