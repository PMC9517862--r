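Package: pahrisk
Title: Toxicity Risk Prioritization for PAH Metabolism and Transformation Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk-entropy prioritization of the metabolism and environmental
    transformation pathways of the 16 USEPA priority polycyclic aromatic
    hydrocarbons (PAHs). Computes toxicity changes of transformation products
    relative to their parent compound across neurotoxic, immunotoxic,
    phytotoxic, developmental, genotoxic, carcinogenic and endocrine
    endpoints, summarizes per-pathway risk probability and risk degree,
    applies an ordinal screening rubric to environmental-risk, human-health
    and environmental-behaviour factors, aggregates them into a total exposed
    risk value per pathway, ranks parents and flags the top fraction as
    high-risk. Also provides the QSAR model-validation statistics (relative
    error, R2, leave-one-out Q2, SEE, F, external R2pred, SEP) with a minimal
    NIPALS partial-least-squares engine, a packaged set of reference
    observed/predicted binding free energies for the three receptor-binding
    models, and a seeded synthetic generator of derivative endpoint tables
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
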