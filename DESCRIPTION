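Package: oleofind
Title: Candidate Gene Discovery for Seed Oil Accumulation from Comparative
    Orthology and Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a candidate-gene inference chain
    for explaining high seed-oil content in oilseed plants. Provides Markov
    clustering (MCL) of weighted graphs, lineage-specific ortholog-group
    classification across a dicot/grass species panel, RPKM normalisation
    and seed-development expression clustering, pathway-level co-expression
    (PLC) candidate prediction, Fisher-exact differential expression between
    sequencing libraries, GO hypergeometric enrichment with GO-slim
    summaries, AW-box promoter scanning, duplication-aware neighbor-joining
    gene-family trees, and a synthetic-data generator with planted truth
    that exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
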