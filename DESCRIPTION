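Package: svmeld
Title: Quality-Aware Consensus Calling of Structural Variants from
    Multiple Short-Read Callers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Merges deletion and insertion calls from multiple short-read
    structural-variant callers into breakpoint-clustered consensus calls,
    harmonizes per-caller quality metrics by normalizing coverage- and
    read-length-dependent values, scores each consensus call with a
    gradient-boosted tree classifier trained to separate true from false
    calls, and writes a probability-ranked consensus VCF. Also provides
    truth-set benchmarking with breakpoint-distance and size-similarity
    matching (precision, recall, F1, ROC AUC, probability-decile tables)
    and a seeded simulator of multi-caller SV call sets for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
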