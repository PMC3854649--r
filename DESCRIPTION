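Package: wsea
Title: Weighted Hypergeometric and Chi-Squared Gene-Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Over-representation analysis of gene sets in which every gene
    contributes to a pathway's enrichment in proportion to a power of its
    absolute log2 fold change. Continuous gene scores are made compatible
    with the discrete hypergeometric distribution through a pseudo-pathway
    construction in which each gene is replicated Q times (Q being the
    pathway's maximum gene score); a weighted chi-squared variant uses the
    unrounded scores directly in a 2x2 contingency table. The standard
    unweighted hypergeometric and chi-squared over-representation tests are
    included as baselines, together with microarray-style preprocessing
    (quantile normalization, pooled-variance t-tests, probe-to-gene
    collapsing), GMT gene-set input/output, a seeded synthetic-data
    generator with planted pathway effects, and a cross-dataset top-k
    consistency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
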