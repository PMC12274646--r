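# End-to-end germline inference: 5'RACE preprocessing, V/J assignment
# against a starting reference, clonal clustering, consensus V inference
# and novel-J discovery, as one convenience wrapper.

#' Run the germline inference pipeline on a read pair set
#'
#' mask primers -> merge pairs -> collapse duplicates (dupcount >= 2) ->
#' assign V/J against the starting reference -> estimate the clonal
#' threshold -> group clones -> infer germline V alleles. Optionally also
#' discovers novel J alleles and/or validates the inferred V set.
#'
#' @param r1,r2 sequence-record tables (R2 in sequencing orientation).
#' @param reference a [germline_set()] with starting V (and J) alleles.
#' @param pset a [primer_set()]; defaults to the built-in 5'RACE primers.
#' @param min_dupcount duplicate-count filter.
#' @param min_support,min_clones clone support rules for
#'   [infer_v_germline()].
#' @param polish re-vote junction-shadow positions and validate read
#'   support against the full collapsed read set ([polish_inferred()]).
#' @param discover_j also run novel-J discovery and database rebuilding.
#' @param validate also run [validate_genotype()] on the inferred set.
#' @param strain,locus labels for outputs.
#' @param ... passed to [infer_v_germline()].
#' @return list: `inferred` (inferred_alleles), `gset` (inferred V as a
#'   [germline_set()]), `j` (rebuild result or NULL), `rearrangements`,
#'   `clones`, `threshold`, `log`, `validation` (or NULL).
#' @export
infer_germline_pipeline <- function(r1, r2, reference,
                                    pset = primer_set(DEFAULT_PRIMERS),
                                    min_dupcount = 2L,
                                    min_support = 0.001, min_clones = 5L,
                                    polish = TRUE,
                                    discover_j = FALSE, validate = FALSE,
                                    strain = NA_character_, locus = "IGK",
                                    ...) {
  pre <- preprocess_reads(r1, r2, pset, min_dupcount = min_dupcount)
  if (nrow(pre$records) == 0L) stop("no reads survived preprocessing")
  rearr <- assign_segments(pre$records, reference, ignore_j = TRUE)
  thr <- suppressWarnings(estimate_clone_threshold(rearr))
  clones <- group_clones(rearr, thr)
  inferred <- infer_v_germline(clones, reference, min_support = min_support,
                               min_clones = min_clones, ...)
  if (polish && nrow(inferred) > 0L) {
    inferred <- polish_inferred(inferred, pre$records_all, reference)
  }
  jres <- NULL
  if (discover_j) {
    jres <- rebuild_and_verify(pre$records, reference, strain = strain)
  }
  val <- NULL
  if (validate) {
    val <- validate_genotype(inferred, pre$records)
    inferred <- val$validated
  }
  list(inferred = inferred,
       gset = as_germline_set(inferred, strain = strain, locus = locus),
       j = jres, rearrangements = clones$rearrangements, clones = clones,
       threshold = thr, log = pre$log, validation = val)
}

#' Compare an inferred set against planted truth
#'
#' Set-level precision and recall by exact sequence equality, for
#' simulation studies.
#'
#' @param inferred a [germline_set()] or `inferred_alleles` (uses
#'   `sequence`).
#' @param truth character vector of true allele sequences.
#' @return list: `precision`, `recall`, `n_inferred`, `n_truth`,
#'   `exact` (TRUE when the sets are identical).
#' @export
recovery_stats <- function(inferred, truth) {
  inf_seqs <- unique(inferred$sequence)
  truth <- unique(truth)
  tp <- sum(inf_seqs %in% truth)
  list(precision = if (length(inf_seqs)) tp / length(inf_seqs) else NA_real_,
       recall = tp / length(truth),
       n_inferred = length(inf_seqs), n_truth = length(truth),
       exact = setequal(inf_seqs, truth))
}
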