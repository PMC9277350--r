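Package: drugaging
Title: Scoring Drug-Induced Effects on Tissue Aging from Transcriptomic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes how cancer drugs may accelerate or protect against
    tissue-level aging by comparing ternary (+1/0/-1) gene signatures.
    Aging-associated signatures are derived from tissue expression profiles by
    Spearman correlation of each gene with donor age; drug-induced signatures
    are derived from replicate post-treatment z-score profiles by a recurrence
    rule. Each matched (drug, tissue) pair is scored with a specificity score,
    a pseudocount-adjusted concordance ratio, and a permutation test with a
    normal-approximated null, and significant aging-accelerating or
    aging-protective events are called. Includes readers for GCT/GCTX/GMT/TSV,
    Fisher's exact overrepresentation of overlap genes, a synthetic-data
    generator with planted ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
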