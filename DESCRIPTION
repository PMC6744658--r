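Package: ppicore
Title: Protein Complex Detection in PPI Networks via Edge Reliability and
    Core-Attachment Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein complexes in protein-protein interaction (PPI)
    networks by exploiting their core-attachment organisation. Edges are first
    scored for reliability with a high-order common-neighbour (HOCN) weight
    built from Jaccard coefficients, and unsupported interactions are
    discarded. Preliminary complex cores are then mined around every protein
    by structural-similarity expansion, candidate attachment proteins are
    classified as peripheral or overlapping from their weighted connectivity
    to each core, and cores plus attachments are assembled into final
    complexes. The package also provides the standard evaluation suite for
    predicted complex sets (neighbourhood-affinity recall, precision,
    F-measure, coverage rate, maximum matching ratio and hypergeometric
    functional-enrichment p-values), a planted-complex network simulator for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
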