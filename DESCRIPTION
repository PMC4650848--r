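Package: polymut
Title: Mutation Detection in Polyploid Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequencing-based detection of chemically induced point mutations in
    polyploid crops from reduced-representation (genotyping-by-sequencing)
    libraries. Implements barcode demultiplexing with restriction-site remnant
    filtering, a seed-and-extend short-read mapper against a unigene
    transcriptome, multi-sample pileup genotyping, and a classifier that
    separates EMS-induced mutations from homoeologous and intervarietal
    sequence differences among subgenomes. Includes downstream mutation
    characterization (transition/transversion spectrum, alleles per unigene,
    synonymous/non-synonymous calls, coverage and depth summaries, saturation
    and extrapolation arithmetic), EST-anchored chromosome-region mapping with
    normalized mutation loads, and a fully synthetic hexaploid GBS simulator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
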