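Package: villusSC
Title: Tag-Based Single-Cell RNA-seq Pipeline for Placental Villus
    Subtype Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for plate-based 3' tag single-cell
    RNA-seq of sorted placental villus cells: demultiplexing of
    barcode/UMI-tagged paired reads, read-1 trimming, UMI deduplication
    and UMI-based TPM quantification, cell- and gene-level quality
    control, Spearman-dissimilarity average-linkage clustering with a
    dynamic hybrid tree cut, marker-panel cell-type annotation with
    sorting-purity rates, cell-cycle classification, Wilcoxon rank-sum
    marker discovery, and curated gene-panel (hormone, imprinted)
    detection.  A negative-binomial synthetic-data generator with
    planted subtypes, cycling cells and low-quality cells makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
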