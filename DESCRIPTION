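Package: zfsubsets
Title: Classification of C2H2 Zinc-Finger Proteins and Symbiosis Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based identification, typing and 11-way subset classification
    of C2H2 zinc-finger proteins from protein sequences or pre-computed domain
    annotation tables, following the plant QALGGH-motif grammar (Q-, M-, Z- and
    D-type fingers; tandem versus dispersed arrangements). Includes downstream
    analyses used in genome-wide family surveys: neighbor-joining phylogeny on
    p-distances with bootstrap supports and subset-wise subtree compression,
    hypergeometric term over/under-representation, tissue expression-pattern
    calls and hierarchical heatmap ordering, relative quantification of qPCR
    data by the delta-delta-Ct method with RNA-seq concordance counting, and
    construction of regulatory networks by intersecting a regulatory map with
    thresholded co-expression edges. A synthetic-data module generates every
    input with planted ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    phangorn,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
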