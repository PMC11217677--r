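Package: hicentropy
Title: Entropy-Based Similarity for Hi-C and Micro-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the similarity of Hi-C and micro-C contact matrices
    through the von Neumann entropy of Pearson-transformed submatrices slid
    along the matrix diagonal. Each chromosome yields an entropy signal; the
    similarity score Q between two matrices is the Pearson correlation of
    their entropy signals, which is robust to sequencing depth and binning
    resolution. Includes readers for cooler (.cool/.mcool) and dense text
    matrices, benchmark aggregation over biological replicates and
    non-replicates, identification of high- and low-complexity genomic
    regions, principal component analysis of entropy signals, and a synthetic
    contact-matrix generator with distance decay, TAD blocks, compartment
    checkerboard structure and finite sequencing depth for fully
    self-contained testing.
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
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
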