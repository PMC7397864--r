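Package: lncscreen
Title: Analysis of Antisense Oligonucleotide lncRNA Knockdown Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing high-throughput antisense oligonucleotide
    (ASO) knockdown screens of long noncoding RNAs with cellular and
    molecular phenotyping: growth-rate estimation from live-cell confluence
    series, knockdown quality control, differential expression against
    matched negative controls, permutation tests of ASO concordance
    (Jaccard index of differentially expressed gene sets), conditional hit
    calling calibrated to an empirical background, motif activity response
    analysis by ridge regression, and preranked gene-set enrichment.
    Includes a synthetic-screen simulator with planted ground truth for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
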