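# 5'RACE read cleanup: primer identification/masking with template-switch
# G-run trimming, ungapped pair merging, and exact duplicate collapsing with
# dupcount bookkeeping.

#' Define a 5' primer set
#'
#' @param primers named character vector of primer sequences (5'->3').
#' @param max_mismatches mismatch tolerance for primer matching.
#' @return a list of class `primer_set`.
#' @export
primer_set <- function(primers, max_mismatches = 2L) {
  if (length(primers) == 0L) stop("primer set must contain at least one primer")
  if (is.null(names(primers)) || any(!nzchar(names(primers))) ||
      anyDuplicated(names(primers)))
    stop("primers must carry unique non-empty names")
  primers <- .norm_seq(primers)
  .check_dna(primers, allow_n = FALSE, what = "primer")
  if (any(!nzchar(primers))) stop("primers must be non-empty")
  structure(list(primers = primers, max_mismatches = as.integer(max_mismatches)),
            class = "primer_set")
}

#' Mask 5' primers and trim the template-switch G-run
#'
#' Locates the best-matching primer by ungapped scan within the first
#' `window` nt of each read (at most `max_mismatches` mismatches), replaces
#' the matched span by `N`, and removes any run of >= 3 G immediately
#' following the primer (the template-switch oligo artifact). Reads with no
#' primer within tolerance are flagged unmatched and left unchanged; they
#' are conventionally excluded downstream.
#'
#' @param records a sequence-record table.
#' @param pset a [primer_set()].
#' @param window search window from the 5' end, in nt.
#' @return `records` with columns `primer` (name or `NA`) and
#'   `primer_matched` added; matched reads have their primer span masked and
#'   G-run removed (qualities are subset accordingly).
#' @export
mask_primers <- function(records, pset, window = 30L) {
  stopifnot(inherits(pset, "primer_set"))
  n <- nrow(records)
  primer <- rep(NA_character_, n)
  matched <- rep(FALSE, n)
  for (i in seq_len(n)) {
    hit <- cpp_scan_primer(records$sequence[i], unname(pset$primers),
                           pset$max_mismatches, window)
    if (!isTRUE(hit$matched)) next
    matched[i] <- TRUE
    primer[i] <- names(pset$primers)[hit$primer]
    pl <- nchar(pset$primers[[hit$primer]])
    s <- records$sequence[i]
    start <- hit$offset + 1L
    end <- hit$offset + pl
    masked <- paste0(substr(s, 1L, start - 1L), strrep("N", pl))
    rest <- substr(s, end + 1L, nchar(s))
    g <- attr(regexpr("^G{3,}", rest), "match.length")
    if (g > 0L) {
      rest <- substr(rest, g + 1L, nchar(rest))
      if (!is.na(records$quality[i])) {
        q <- records$quality[i]
        records$quality[i] <- paste0(substr(q, 1L, end), substr(q, end + g + 1L, nchar(q)))
      }
    }
    records$sequence[i] <- paste0(masked, rest)
  }
  records$primer <- primer
  records$primer_matched <- matched
  records
}

#' Merge a read pair by its best ungapped overlap
#'
#' `r2` is given in sequencing orientation and reverse-complemented
#' internally. The best overlap of length >= `min_overlap` with mismatch
#' fraction <= `max_error_rate` is chosen (columns with `N` are neutral);
#' among qualifying overlaps the one with the most matching columns wins.
#' Disagreements resolve toward the higher-quality base, ties toward r1.
#' Failure to merge is a reported outcome, not an error.
#'
#' @param r1,r2 single-row sequence-record tables, or lists with `sequence`
#'   and optional `quality`.
#' @param min_overlap minimum overlap length in nt.
#' @param max_error_rate maximum mismatch fraction inside the overlap.
#' @return list with `success`, and on success `sequence`, `quality`,
#'   `overlap`, `mismatches`.
#' @export
merge_pair <- function(r1, r2, min_overlap = 20L, max_error_rate = 0.1) {
  s1 <- r1$sequence[1]; s2 <- revcomp(r2$sequence[1])
  q1 <- r1$quality[1]; q2 <- r2$quality[1]
  if (is.na(q1) || is.na(q2)) { q1 <- ""; q2 <- "" }
  else q2 <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  cpp_merge_pair(s1, q1, s2, q2, as.integer(min_overlap), max_error_rate)
}

#' Merge all read pairs of a repertoire
#'
#' @param r1,r2 sequence-record tables with matching ids (pair order).
#' @inheritParams merge_pair
#' @return list with `merged` (sequence-record table of successfully merged
#'   reads) and `n_failed`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_error_rate = 0.1) {
  if (nrow(r1) != nrow(r2)) stop("r1 and r2 must have the same number of reads")
  if (!all(r1$id == r2$id)) stop("r1 and r2 ids must match pairwise")
  keep_id <- character(0); keep_seq <- character(0); keep_q <- character(0)
  n_failed <- 0L
  has_q <- !anyNA(r1$quality) && !anyNA(r2$quality)
  r2rc <- revcomp(r2$sequence)
  r2q <- if (has_q) vapply(strsplit(r2$quality, ""), function(x)
    paste(rev(x), collapse = ""), "") else rep("", nrow(r2))
  r1q <- if (has_q) r1$quality else rep("", nrow(r1))
  out <- vector("list", nrow(r1))
  for (i in seq_len(nrow(r1))) {
    m <- cpp_merge_pair(r1$sequence[i], r1q[i], r2rc[i], r2q[i],
                        as.integer(min_overlap), max_error_rate)
    if (isTRUE(m$success)) {
      out[[i]] <- c(r1$id[i], m$sequence, if (has_q) m$quality else NA_character_)
    } else n_failed <- n_failed + 1L
  }
  out <- out[!vapply(out, is.null, TRUE)]
  merged <- if (length(out)) {
    mat <- do.call(rbind, out)
    seq_records(mat[, 1], mat[, 2], quality = mat[, 3])
  } else seq_records(character(), character())
  list(merged = merged, n_failed = n_failed)
}

#' Collapse exact duplicate reads
#'
#' Groups records with identical sequences into one record whose `dupcount`
#' is the group size (weighted by incoming dupcounts), then removes records
#' with `dupcount < min_dupcount`. Before filtering, the dupcount total
#' equals the number of input reads.
#'
#' @param records a sequence-record table.
#' @param min_dupcount minimum duplicate count retained (the conventional
#'   evidence filter is 2: a sequence must be seen at least twice).
#' @return list with `records` (collapsed and filtered; representative id =
#'   lexicographically smallest member id), `n_input`, `n_unique`,
#'   `n_retained`.
#' @export
collapse_duplicates <- function(records, min_dupcount = 2L) {
  if (nrow(records) == 0L)
    return(list(records = records, n_input = 0L, n_unique = 0L, n_retained = 0L))
  grp <- factor(records$sequence, levels = unique(records$sequence))
  counts <- as.integer(rowsum(records$dupcount, grp))
  rep_id <- vapply(split(records$id, grp), function(ids) sort(ids)[1], "")
  rep_q <- vapply(split(seq_len(nrow(records)), grp), function(ix) {
    q <- records$quality[ix]
    q <- q[!is.na(q)]
    if (length(q)) q[1] else NA_character_
  }, "")
  collapsed <- seq_records(rep_id, levels(grp), quality = rep_q, dupcount = counts)
  collapsed <- collapsed[order(collapsed$id), , drop = FALSE]
  rownames(collapsed) <- NULL
  keep <- collapsed$dupcount >= min_dupcount
  list(records = collapsed[keep, , drop = FALSE],
       n_input = sum(records$dupcount),
       n_unique = nrow(collapsed),
       n_retained = sum(keep))
}

#' Run the full 5'RACE preprocessing chain
#'
#' mask primers -> drop unmatched reads -> merge pairs -> collapse
#' duplicates -> dupcount filter, with per-stage counts.
#'
#' @param r1,r2 sequence-record tables (R2 in sequencing orientation).
#' @param pset a [primer_set()].
#' @inheritParams merge_pair
#' @inheritParams collapse_duplicates
#' @return list with `records` (collapsed reads) and `log` (data.frame of
#'   per-stage read counts).
#' @export
preprocess_reads <- function(r1, r2, pset, min_overlap = 20L,
                             max_error_rate = 0.1, min_dupcount = 2L) {
  masked <- mask_primers(r1, pset)
  keep <- masked$primer_matched
  mg <- merge_pairs(masked[keep, , drop = FALSE],
                    r2[keep, , drop = FALSE],
                    min_overlap = min_overlap, max_error_rate = max_error_rate)
  cl_all <- collapse_duplicates(mg$merged, min_dupcount = 1L)
  cl <- collapse_duplicates(mg$merged, min_dupcount = min_dupcount)
  log <- data.frame(
    stage = c("input", "primer_matched", "merged", "unique", "dupcount_filtered"),
    reads = c(nrow(r1), sum(keep), nrow(mg$merged), cl$n_unique, cl$n_retained))
  list(records = cl$records, records_all = cl_all$records, log = log)
}
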