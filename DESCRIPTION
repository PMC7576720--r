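Package: dktax
Title: Taxonomic Classification of Error-Prone Long Reads with Discriminative K-Mers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a discriminative k-mer reference database from genomes and
    an NCBI-style taxonomy (species-level deduplication, genus-level collision
    assignment, uniform positional subsampling, cross-taxon removal) and
    classifies long, error-prone reads by approximate k-mer matching: exact
    prefix grouping, seed-masked quick matching tolerating one substitution,
    and banded dynamic programming tolerating two further errors including
    indels. Includes a long-read simulator with a configurable
    substitution/insertion/deletion error model and the standard
    sensitivity/precision/F1 evaluation at genus and species rank.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
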