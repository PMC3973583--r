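Package: amaresist
Title: Detecting Alpha-Amanitin-Resistance Mechanisms from Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis chain for detecting candidate toxin-resistance
    mechanisms from gene expression data in Drosophila melanogaster:
    rank-product differential expression with a permutation null, a
    sliding-bin binomial coincidence scan for genomic clusters of
    differentially expressed genes, hypergeometric term and protein-domain
    enrichment with enrichment-factor statistics, logarithmic-trendline
    LC50 estimation from dose-response survival assays, and a
    randomization test for reference-gene-normalized qPCR expression
    ratios. A synthetic-data generator emulates the statistical structure
    of the study design so every stage is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
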