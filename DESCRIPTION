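Package: tidescope
Title: Metabolic Task Scoring and Condition-Specific Flux Analysis from
    Paired Transcriptomics and Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates paired transcriptomics and metabolomics data with a
    genome-scale metabolic network reconstruction. Implements metabolic-task
    scoring from differential expression (TIDEs) with a shuffled-weight
    permutation null, a metabolomics preprocessing and produced/consumed
    classification chain against blank-media controls, metabolite-driven
    tailoring of a tissue model with an auditable curation ledger, and
    transcript-guided extraction of condition-specific models followed by
    flux sampling, Bray-Curtis ordination and random-forest ranking of
    condition-distinguishing reactions. Includes a synthetic-data generator
    that produces every pipeline input with known ground truth, a
    flux-balance analysis core (FBA, parsimonious FBA, task feasibility,
    hit-and-run flux sampling) and readers/writers for SBML Level 3 FBC and
    a documented JSON model dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    MASS,
    jsonlite,
    yaml,
    xml2,
    withr,
    vegan,
    ranger,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
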