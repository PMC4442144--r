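Package: ligzip
Title: Splint-Ligation Probe Design and Long-Range Isoform Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for RNA-templated DNA-DNA ligation assays that compress
    long-range exon connectivity of alternatively spliced mRNAs into short,
    sequenceable DNA products. Designs splint oligonucleotide ('ligamer')
    pools against a gene model using nearest-neighbor duplex thermodynamics,
    enumerates mutually exclusive exon isoforms and the expected
    ligation-product index, simulates control experiments (isoform mixtures,
    template switching, near-cognate ligation, paired-end reads), decodes
    paired reads into isoform count tables via barcode anchoring, and tests
    exon-combination coordination against independence with exact binomial
    tests and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
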