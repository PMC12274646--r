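# Affine-gap pairwise alignment exposed to R. The DP core lives in
# src/align.cpp; scoring defaults are match +1, mismatch -2, gap open -4,
# gap extend -1 (a gap of length k costs open + k*extend).

#' Alignment scoring scheme
#'
#' @param match,mismatch,gap_open,gap_extend integer scoring parameters.
#' @return a named list used by [align()].
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                          gap_extend = -1L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

.mode_code <- function(mode) {
  switch(mode, global = 0L, glocal = 1L, local = 2L,
         stop("unknown alignment mode: ", mode))
}

#' Pairwise sequence alignment
#'
#' Optimal alignment under affine-gap scoring. `"global"` aligns both
#' sequences end to end; `"glocal"` aligns the full query within the
#' reference (terminal reference gaps are free); `"local"` is
#' Smith-Waterman. Traceback ties prefer diagonal, then up (query base
#' against a gap), then left, so results are deterministic.
#'
#' When `n_wildcard` is `TRUE` (the default, for DNA) an `N` in either
#' sequence scores 0 against anything and the column counts neither as a
#' match nor a mismatch, keeping primer-masked bases neutral. Disable it for
#' amino-acid alignments, where `N` is asparagine.
#'
#' Percent identity is `100 * matches / columns`, where columns are the
#' aligned columns excluding terminal gaps and (with `n_wildcard`) excluding
#' N-columns; internal gap columns count in the denominator.
#'
#' @param query,reference sequences (character scalars).
#' @param mode `"global"`, `"glocal"` or `"local"`.
#' @param scoring an [align_scoring()] list.
#' @param n_wildcard treat `N` as a neutral wildcard.
#' @param check_alphabet reject characters outside A/C/G/T/N (set `FALSE`
#'   for amino-acid input).
#' @return a list of class `alignment` with elements `score`, `q_start`,
#'   `q_end`, `r_start`, `r_end` (0-based half-open spans), `matches`,
#'   `mismatches`, `gaps`, `percent_identity`, `columns`, and the aligned
#'   column maps `qpos`/`rpos` (0-based positions, -1 for a gap).
#' @export
align <- function(query, reference, mode = c("global", "glocal", "local"),
                  scoring = align_scoring(), n_wildcard = TRUE,
                  check_alphabet = n_wildcard) {
  mode <- match.arg(mode)
  if (!nzchar(query) || !nzchar(reference))
    stop("both sequences must be non-empty")
  if (check_alphabet) {
    .check_dna(c(query, reference), allow_n = TRUE)
  }
  res <- cpp_align(query, reference, .mode_code(mode), scoring$match,
                   scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                   n_wildcard)
  res$percent_identity <-
    if (res$n_columns > 0) 100 * res$matches / res$n_columns else NA_real_
  res$mode <- mode
  class(res) <- "alignment"
  res
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("%s alignment: score %d, identity %.2f%% (%d match / %d mismatch / %d gap)\n",
              x$mode, x$score,
              if (is.na(x$percent_identity)) NaN else x$percent_identity,
              x$matches, x$mismatches, x$gaps))
  cat(sprintf("  query [%d,%d)  reference [%d,%d)\n",
              x$q_start, x$q_end, x$r_start, x$r_end))
  invisible(x)
}

# Score-only alignment of many queries against one reference; used to pick
# the best allele before running a full traceback on the winner.
align_scores <- function(queries, reference, mode, scoring = align_scoring(),
                         n_wildcard = TRUE) {
  cpp_score_batch(queries, reference, .mode_code(mode), scoring$match,
                  scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                  n_wildcard)
}

#' Percent identity between two sequences
#'
#' Convenience wrapper around [align()] returning only the identity.
#'
#' @inheritParams align
#' @export
percent_identity <- function(query, reference, mode = "global", ...) {
  align(query, reference, mode = mode, ...)$percent_identity
}
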