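Package: kinmatrix
Title: Pedigree, Genomic and Combined Relationship Matrices for Diploid
    and Autopolyploid Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of genetic relationship matrices for diploid and
    autopolyploid organisms: pedigree-expectation numerator relationship
    matrices (additive and dominance, with double reduction for even
    ploidies and support for non-deterministic polycross pedigrees),
    marker-based realized relationship matrices under the common additive,
    dominance, digenic and full-autopolyploid parametrizations, and
    single-step combined (H) matrices blending pedigree and genomic
    information. Includes allele-dosage marker quality control and
    imputation, a gene-dropping Monte-Carlo engine that serves as the
    identity-by-descent oracle for the pedigree expectations, readers and
    writers for the standard pedigree, dosage and labelled-matrix formats,
    and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
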