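Package: bsamapr
Title: Bulked Segregant Analysis Scans and Fine-Mapping of a Dominant Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-mapping toolkit for a single dominant locus mapped with
    pooled sequencing of phenotype-selected bulks, modelled on the workflow
    used to localize the dominant fuzzless gene of Gossypium arboreum.
    Provides Mendelian segregation tests, BSA-Seq genome scans (SNP-index,
    delta SNP-index and Euclidean-distance statistics) with tricube-window
    smoothing, median + 3*SD thresholding and candidate-region intersection,
    recombinant-marker interval narrowing, differential-expression filtering
    (FPKM, t-test, Benjamini-Hochberg FDR), coding/promoter variant
    consequence calls, and candidate-gene ranking. A synthetic F2/BC1
    pooled-sequencing and expression generator supplies data with the
    statistical structure the scan assumes, so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
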