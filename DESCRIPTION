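Package: airrgerm
Title: Germline Immunoglobulin Light-Chain Allele Inference from AIRR-seq Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring germline immunoglobulin kappa and lambda
    variable (V) and joining (J) gene alleles from 5'RACE adaptive immune
    receptor repertoire sequencing (AIRR-seq) reads, without relying on
    external aligner or inference binaries. Includes 5'RACE read
    preprocessing (primer masking, template-switch G-run trimming, pair
    merging, duplicate collapsing), an affine-gap aligner for V/J segment
    assignment, clonal clustering with per-sample distance-to-nearest
    thresholds, consensus-based novel V allele inference with a clone
    support rule, frequency-based novel J allele discovery, inter-strain
    germline-set comparison (database representation, exact-sequence
    sharing sets, best-match mean-identity matrices with hierarchical
    clustering), SNP-based haplotype grouping via neighbor joining, and
    amino-acid divergence analysis of V genes. A self-contained repertoire
    simulator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
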