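Package: phenoflux
Title: Enzyme-Promiscuity Extension and Contextual Analysis of Gut
    Microbiota Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to extend a gut-microbiota metabolic reconstruction with
    predicted degradation reactions for dietary phenolic compounds and to
    analyse the metabolic capabilities of the extended network.  Reaction
    rules expressed as SMARTS transformations are applied to source
    compounds under biological and chemical similarity cutoffs, predicted
    mono-substrate transformations are completed with template co-substrates
    and balanced at the atomic level, and a guided biosensor-mode search
    connects source compounds to the metabolites of the known network.
    Predicted reactions are integrated by sequential weighted-FASTCORE
    gap-filling with flux-variability-based consistency cleanup, and
    compartmentalized community models contextualized with food composition
    and per-sample species presence predict output microbial metabolites,
    validated against presence/absence metabolomics with an exact Fisher
    test.  A synthetic-data generator with planted ground truth supports
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, available as "python" on
    the PATH (used for structure standardization, SMARTS rule application
    and fingerprint similarity).
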