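Package: kinoscope
Title: Peptide-Array Kinome Profiling and Kinase-Inhibitor Viability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peptide kinase-substrate microarrays
    (spot quality control, background correction, cross-array quantile
    normalization, median-of-triplicate summarization), upstream kinase
    activity inference from top phosphorylated substrates, empirical-Bayes
    moderated t contrasts between sample groups, hypergeometric pathway
    over-representation, and plate-reader viability analysis with
    four-parameter-logistic dose-response fits, censored absolute IC50
    estimation, and Bliss-independence drug-combination enhancement
    statistics. Includes a synthetic-data generator with planted ground
    truth so every stage is testable without laboratory inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
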