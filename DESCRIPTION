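Package: lncirc
Title: lncRNA and circRNA Landscape Analysis for Divergent-Line Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the downstream analysis of long non-coding
    RNA (lncRNA) and circular RNA (circRNA) landscapes in two-group designs
    such as fat-line versus lean-line broilers: candidate filtering and
    coding-potential consensus, positional classification of lncRNAs (six
    classes) and circRNAs (five classes) against a coding annotation,
    presence filtering and differential-expression screening with
    line-specificity flags, cis/trans target prediction, co-expression and
    competing-endogenous-RNA (ceRNA) network construction with hub ranking,
    hypergeometric term enrichment with rich factors, and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
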