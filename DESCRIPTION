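Package: sigconnect
Title: Transcriptome Signature Connectivity Scoring for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds up/down gene signatures from differential-expression
    tables or treated/control expression matrices, represents drug
    perturbation experiments as ranked probe profiles, and scores
    signatures against an instance database with the bidirectional
    Kolmogorov-Smirnov connectivity statistic: per-instance raw scores,
    database-wide scaling to [-1, 1] connectivity scores, compound-level
    similarity means, instance-set enrichment, empirical permutation
    p-values, and candidate ranking. Includes second-order drug-similarity
    queries for mechanism-of-action inference, a synthetic perturbation
    database simulator with planted concordant/oppositional compounds for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
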