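# V/J segment assignment of processed reads against a germline set.
# V alleles are aligned glocally (allele global, read local), so masked
# primer Ns at the read 5' absorb truncated allele starts neutrally; J
# alleles are aligned locally in the read region 3' of the V.

J_SEARCH_SLACK <- 3L   # J may start up to 3 nt inside the V span (junction trim)

#' Assign V and J segments to processed reads
#'
#' For every read the V allele with the best glocal score is chosen (ties
#' resolve to the lexicographically smallest allele name), then J alleles
#' are aligned locally within the read region 3' of the V span. With
#' `ignore_j = TRUE` (the default, matching germline-inference practice)
#' reads without a J match are kept; otherwise they are dropped.
#'
#' `v_identity` is recomputed from the V profile (see below) over genuinely
#' covered, non-masked positions, so junction-derived noise at the V 3' end
#' does not depress it.
#'
#' Alongside the rearrangement table the function returns, as attribute
#' `v_profiles`, one profile per read: the read bases mapped onto the
#' coordinates of the called V allele (NA where uncovered or masked), plus
#' `delta`, the offset between the observed J start and the position where
#' the J would start had the V 3' end not been trimmed. `delta` bounds the
#' possible junction trim and drives the down-weighting of V 3'-end
#' ("junction shadow") votes during consensus building.
#'
#' @param records a sequence-record table (typically collapsed reads).
#' @param gset a [germline_set()] with at least one V allele.
#' @param ignore_j keep reads lacking a J assignment.
#' @param j_min_score minimum local alignment score for a J call.
#' @param scoring an [align_scoring()] list.
#' @param prefilter shortlist V alleles by their best ungapped placement
#'   score (exact for substitution-only differences) before running the
#'   affine-gap DP; `prefilter_margin` controls how far below the best
#'   ungapped score an allele may fall and still reach the exact DP.
#' @param prefilter_margin score margin for the shortlist.
#' @return a rearrangement table with attribute `v_profiles` (named list).
#' @export
assign_segments <- function(records, gset, ignore_j = TRUE,
                            j_min_score = 12L, scoring = align_scoring(),
                            prefilter = TRUE, prefilter_margin = 9L) {
  v <- gset[gset$segment == "V", , drop = FALSE]
  j <- gset[gset$segment == "J", , drop = FALSE]
  if (nrow(v) == 0L) stop("germline set contains no V alleles")
  v_ord <- order(v$name)
  v <- v[v_ord, , drop = FALSE]          # ties -> smallest name wins
  j <- j[order(j$name), , drop = FALSE]
  v_chars <- strsplit(v$sequence, "")

  n <- nrow(records)
  o_vcall <- character(n); o_jcall <- character(n)
  o_vid <- numeric(n); o_vs <- integer(n); o_ve <- integer(n)
  o_js <- rep(NA_integer_, n); o_je <- rep(NA_integer_, n)
  o_jr <- character(n)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    read <- records$sequence[i]
    if (prefilter) {
      pre <- cpp_offset_scores(v$sequence, read, scoring$match,
                               scoring$mismatch, as.integer(prefilter_margin))
      short <- which(pre >= max(pre) - prefilter_margin)
      if (max(pre) < -1e8) short <- seq_len(nrow(v))  # reads shorter than alleles
    } else short <- seq_len(nrow(v))
    if (length(short) == 1L) {
      vi <- short
    } else {
      scores <- rep(-Inf, nrow(v))
      scores[short] <- align_scores(v$sequence[short], read, mode = "glocal",
                                    scoring = scoring)
      vi <- which(scores == max(scores))[1] # v sorted by name: first max wins
    }
    aln <- align(v$sequence[vi], read, mode = "glocal", scoring = scoring)
    # J search 3' of the V span (allowing slack for junction-trimmed V tails)
    j_call <- ""; j_s <- NA_integer_; j_e <- NA_integer_
    j_raw <- NA_integer_; delta <- NA_integer_
    if (nrow(j) > 0L) {
      s0 <- max(0L, aln$r_end - J_SEARCH_SLACK)
      region <- substr(read, s0 + 1L, nchar(read))
      if (nzchar(region)) {
        jscores <- align_scores(j$sequence, region, mode = "local", scoring = scoring)
        ji <- which(jscores == max(jscores))[1]
        if (jscores[ji] >= j_min_score) {
          jaln <- align(j$sequence[ji], region, mode = "local", scoring = scoring)
          j_call <- j$name[ji]
          j_raw <- s0 + jaln$r_start
          j_s <- j_raw
          # anchor the stored J end to the full extent of the called J on
          # the read: local alignment clips trailing mismatches, which
          # would hide polymorphisms in the last bases of a J segment
          # (the J 3' end abuts the constant region and is never trimmed)
          j_e <- min(nchar(read),
                     j_s + nchar(j$sequence[ji]) - jaln$q_start)
        }
      }
    }
    prof <- .v_profile(aln, v_chars[[vi]], read, j_raw)
    profiles[[i]] <- prof
    # the V span may extend into the junction when the molecule's V 3' end
    # was trimmed; the J offset proves at least t_min such positions, so
    # the stored V end is pulled back accordingly
    t_min <- if (is.na(prof$delta)) 0L else max(0L, -prof$delta)
    v_e <- aln$r_end - t_min
    if (!is.na(j_s)) {
      delta <- prof$delta
      j_s <- max(j_s, v_e)             # stored J interval never precedes v_end
      if (j_s >= j_e) { j_call <- ""; j_s <- NA_integer_; j_e <- NA_integer_ }
    }
    jr <- if (!is.na(j_e)) substr(read, v_e + 1L, j_e)
    else substr(read, v_e + 1L, nchar(read))
    o_vcall[i] <- v$name[vi]; o_jcall[i] <- j_call
    o_vid[i] <- prof$identity
    o_vs[i] <- aln$r_start; o_ve[i] <- v_e
    o_js[i] <- j_s; o_je[i] <- j_e; o_jr[i] <- jr
  }
  df <- data.frame(
    sequence_id = records$id, sequence = records$sequence,
    v_call = o_vcall, j_call = o_jcall, v_identity = o_vid,
    v_start = o_vs, v_end = o_ve, j_start = o_js, j_end = o_je,
    j_region = o_jr, clone_id = NA_character_,
    dupcount = records$dupcount, stringsAsFactors = FALSE)
  names(profiles) <- records$id
  if (!ignore_j) {
    keep <- df$j_call != ""
    profiles <- profiles[keep]
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df <- validate_rearrangements(df)
  attr(df, "v_profiles") <- profiles
  df
}

# Map read bases onto allele coordinates from a glocal alignment.
# Returns bases (character vector, NA where uncovered/masked/gap), the
# identity over covered positions, and delta = (0-based J start) - 1 -
# (read position of the allele's last base): delta = insert_len - trim, so
# trim >= max(0, -delta). Positions provably inside the junction trim are
# blanked; when no J was found the last JUNCTION_SHADOW positions are
# blanked conservatively.
JUNCTION_SHADOW <- 3L

.v_profile <- function(aln, allele, read, j_start_raw) {
  ref <- if (length(allele) > 1L) allele else strsplit(allele, "")[[1]]
  L <- length(ref)
  bases <- rep(NA_character_, L)
  qp <- aln$qpos; rp <- aln$rpos
  keep <- qp >= 0L & rp >= 0L
  qpk <- qp[keep]; rpk <- rp[keep]
  b <- substring(read, rpk + 1L, rpk + 1L)
  ok <- b != "N"
  bases[qpk[ok] + 1L] <- b[ok]
  rposL <- if (length(qpk) && any(qpk == L - 1L)) rpk[qpk == L - 1L][1] else NA_integer_
  delta <- if (!is.na(j_start_raw) && !is.na(rposL)) j_start_raw - 1L - rposL
  else NA_integer_
  # blank positions provably inside the junction trim; without a located J
  # the shadow is kept but receives zero weight in consensus voting
  t_min <- if (is.na(delta)) 0L else max(0L, -delta)
  if (t_min > 0L) bases[seq.int(L - t_min + 1L, L)] <- NA_character_
  cov <- !is.na(bases)
  identity <- if (any(cov)) 100 * sum(bases[cov] == ref[cov]) / sum(cov)
  else NA_real_
  list(bases = bases, delta = delta, identity = identity,
       covered = sum(cov))
}

# posterior-style weight that a member's base at allele position p is
# genuine (junction trim t <= L - p), given delta = insert - trim with
# trim uniform on 0..3 and insert uniform on 0..4
.shadow_weight <- function(delta, k) {
  if (is.na(delta)) return(0)
  ts <- 0:3
  valid <- ts + delta >= 0 & ts + delta <= 4
  if (!any(valid)) return(0)
  sum(ts[valid] <= k) / sum(valid)
}
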