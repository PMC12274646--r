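# Reported novel light-chain J alleles and the bundled stand-in reference
# J set used to verify them. The reference file is a reconstructed
# stand-in (synthetic, assembled from well-known mouse J segment
# sequences), shipped because the analysis must run without network access
# to a curated database.

#' Reported novel J alleles
#'
#' The three novel light-chain J alleles identified across wild-derived
#' mouse strains: a novel IGKJ2 (shared by PWD/PhJ and MSM/MsJ), a novel
#' IGLJ1 (LEWES/EiJ) and a novel IGLJ2 (MSM/MsJ), each a single-nucleotide
#' variant of its reference allele.
#'
#' @return a data.frame with `name`, `strain`, `sequence`.
#' @export
novel_j_alleles <- function() {
  data.frame(
    name = c("IGKJ2_novel", "IGLJ1_novel", "IGLJ2_novel"),
    strain = c("PWD/PhJ+MSM/MsJ", "LEWES/EiJ", "MSM/MsJ"),
    sequence = c(
      "TGTACACGTTCGGATCGGGGACCAAGCTGGAAATAAAAC",
      "CTGGGTGTTCGGTGGAGGAACCAAATTGACTGTCCTAG",
      "TTATGTTTTCGGCAGTGGAACCAAGGTCACTGTCCTAG"),
    stringsAsFactors = FALSE)
}

#' Load the bundled stand-in reference J allele set
#'
#' A small synthetic stand-in for the curated mouse kappa/lambda J allele
#' database (see the package's extdata). Intended for worked examples and
#' tests; it is not the curated database itself.
#'
#' @return a [germline_set()] of J alleles (locus attribute is `IGK` for
#'   kappa entries and `IGL` for lambda ones; both are included with
#'   segment `"J"`).
#' @export
reference_j_standin <- function() {
  path <- system.file("extdata", "reference_j_standin.fasta",
                      package = "airrgerm")
  rec <- read_sequences(path, format = "fasta")
  germline_set(rec$id, rec$sequence, segment = "J", locus = "IGK",
               status = "reference")
}

#' Count substitutions between a novel allele and its nearest reference J
#'
#' Aligns the query globally within each reference (glocal) and returns the
#' nearest reference with its substitution (mismatch) and gap counts.
#'
#' @param sequence nucleotide sequence of the candidate allele.
#' @param reference_js a [germline_set()] of J alleles.
#' @return list: `nearest`, `substitutions`, `gaps`.
#' @export
novel_j_substitutions <- function(sequence, reference_js = reference_j_standin()) {
  refs <- reference_js[reference_js$segment == "J", , drop = FALSE]
  alns <- lapply(refs$sequence, function(r) align(sequence, r, mode = "global"))
  mm <- vapply(alns, function(a) a$mismatches + a$gaps, 0L)
  best <- which(mm == min(mm))
  best <- best[order(refs$name[best])][1]
  list(nearest = refs$name[best],
       substitutions = alns[[best]]$mismatches,
       gaps = alns[[best]]$gaps)
}
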