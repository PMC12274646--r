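# Novel J allele discovery: frequency analysis of J-region strings that are
# not exact sub-sequences of any reference J allele, followed by database
# rebuilding and re-assignment until no new candidate emerges.

#' Extract the J region of a rearrangement
#'
#' `mode = "junction"` returns the read segment from the end of the V
#' alignment to the end of the J alignment (or the read end when no J was
#' assigned): the junction insert plus the (possibly 5'-trimmed) J.
#' `mode = "aligned_j"` returns only the J-aligned read substring, which is
#' the form used for novel-J candidate counting (junction inserts would
#' otherwise fragment the counts).
#'
#' @param rearr a rearrangement table.
#' @param mode `"junction"` or `"aligned_j"`.
#' @return character vector of J-region strings (may be empty strings).
#' @export
extract_j_region <- function(rearr, mode = c("junction", "aligned_j")) {
  mode <- match.arg(mode)
  if (mode == "junction") {
    end <- ifelse(is.na(rearr$j_end), nchar(rearr$sequence), rearr$j_end)
    substr(rearr$sequence, rearr$v_end + 1L, end)
  } else {
    out <- rep("", nrow(rearr))
    has <- !is.na(rearr$j_start)
    out[has] <- substr(rearr$sequence[has], rearr$j_start[has] + 1L,
                       rearr$j_end[has])
    out
  }
}

#' Discover novel J alleles by frequency analysis
#'
#' Counts distinct J-aligned read substrings weighted by dupcount. Strings
#' that are exact substrings of a reference J allele are dismissed; the
#' remainder are grouped into substring-related families (junction trimming
#' makes one novel segment appear as several 5'-trimmed variants), and a
#' family whose summed frequency exceeds `min_freq` yields one candidate:
#' its longest member whose own frequency is coherent with the modal
#' variant. Candidates are named provisionally after their nearest
#' reference allele (`<nearest>_S<k>`).
#'
#' @param rearr a rearrangement table (with J assignments).
#' @param reference_js a [germline_set()] (or data.frame) with J alleles.
#' @param min_freq frequency threshold (the "rate > 1 percent" rule).
#' @param strain optional strain label recorded on the candidates.
#' @param weight_by_dupcount weight string frequencies by `dupcount`
#'   (read-weighted); `FALSE` counts unique collapsed sequences instead.
#' @param min_variants minimal number of distinct member strings a family
#'   needs; junction trimming gives a genuine novel segment several
#'   5'-trimmed variants, whereas a single hypermutated molecule amplified
#'   to high dupcount yields only one.
#' @return data.frame of class `j_candidates`: `name`, `sequence`,
#'   `frequency`, `nearest_reference`, `n_mismatches`, `strain`, ordered by
#'   frequency (desc) then sequence.
#' @export
discover_novel_j <- function(rearr, reference_js, min_freq = 0.01,
                             strain = NA_character_,
                             weight_by_dupcount = TRUE, min_variants = 2L) {
  refs <- reference_js[reference_js$segment == "J", , drop = FALSE]
  if (nrow(refs) == 0L) stop("reference J set is empty")
  jr <- extract_j_region(rearr, mode = "aligned_j")
  keep <- nzchar(jr)
  jr <- jr[keep]
  w <- if (weight_by_dupcount) rearr$dupcount[keep] else rep(1L, sum(keep))
  total <- sum(w)
  if (total == 0L) return(.empty_j_candidates())
  freq <- tapply(w, jr, sum) / total
  obs <- names(freq)
  in_ref <- vapply(obs, function(s)
    any(vapply(refs$sequence, function(r) grepl(s, r, fixed = TRUE), TRUE)), TRUE)
  obs <- obs[!in_ref]; freq <- unname(freq[!in_ref])
  if (!length(obs)) return(.empty_j_candidates())
  # Group observed strings around their most frequent member: junction
  # trimming makes the same novel segment appear as a family of 5'-trimmed
  # variants (plus rare chance-extended ones), all related by the substring
  # relation. Each group's frequency is the summed frequency of its
  # members; the reported representative is the longest member whose own
  # frequency is coherent with the modal variant (rare chance extensions
  # are thereby excluded).
  claimed <- rep(FALSE, length(obs))
  accepted <- character(0); accepted_freq <- numeric(0)
  ord <- order(-freq, obs)
  for (i in ord) {
    if (claimed[i]) next
    m <- obs[i]
    rel <- !claimed & (vapply(obs, function(t)
      grepl(t, m, fixed = TRUE) || grepl(m, t, fixed = TRUE), TRUE))
    agg <- sum(freq[rel])
    claimed[rel] <- TRUE
    if (agg <= min_freq) next
    grp <- which(rel)
    if (length(grp) < min_variants) next
    coherent <- grp[freq[grp] >= 0.15 * freq[i]]
    rep_i <- coherent[order(-nchar(obs[coherent]), obs[coherent])][1]
    accepted <- c(accepted, obs[rep_i])
    accepted_freq <- c(accepted_freq, agg)
  }
  if (!length(accepted)) return(.empty_j_candidates())
  near_name <- character(length(accepted)); near_mm <- integer(length(accepted))
  for (i in seq_along(accepted)) {
    alns <- lapply(refs$sequence, function(r)
      align(accepted[i], r, mode = "glocal"))
    mm <- vapply(alns, function(a) a$mismatches + a$gaps, 0L)
    best <- which(mm == min(mm))
    best <- best[order(refs$name[best])][1]
    near_name[i] <- refs$name[best]
    near_mm[i] <- mm[best]
  }
  cnt <- integer(0)
  nm <- character(length(accepted))
  for (i in order(-accepted_freq, accepted)) {
    k <- if (near_name[i] %in% names(cnt)) cnt[[near_name[i]]] + 1L else 1L
    cnt[near_name[i]] <- k
    nm[i] <- sprintf("%s_S%d", near_name[i], k)
  }
  out <- data.frame(name = nm, sequence = accepted,
                    frequency = accepted_freq,
                    nearest_reference = near_name, n_mismatches = near_mm,
                    strain = strain, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("j_candidates", "data.frame")
  out
}

.empty_j_candidates <- function() {
  out <- data.frame(name = character(), sequence = character(),
                    frequency = numeric(), nearest_reference = character(),
                    n_mismatches = integer(), strain = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("j_candidates", "data.frame")
  out
}

#' Rebuild the J database with candidates and re-assign until stable
#'
#' Adds discovered candidates to the reference J set, re-assigns all reads,
#' and repeats discovery until no new candidate emerges (the candidate set
#' grows monotonically and is bounded by the distinct J-region strings, so
#' the iteration terminates). Reports how many reads changed their J call
#' and how many still lack one.
#'
#' @param records collapsed reads (sequence-record table).
#' @param gset a [germline_set()] with the V alleles and reference J
#'   alleles used for assignment.
#' @param min_freq candidate frequency threshold.
#' @param strain optional strain label.
#' @param max_iter safety bound on discovery rounds.
#' @return list with `gset` (augmented germline set), `rearrangements`
#'   (final assignment), `candidates` (all accepted candidates) and
#'   `report` (data.frame per iteration: new candidates, J calls changed,
#'   reads without J).
#' @export
rebuild_and_verify <- function(records, gset, min_freq = 0.01,
                               strain = NA_character_, max_iter = 10L) {
  rearr <- assign_segments(records, gset, ignore_j = TRUE)
  all_cand <- .empty_j_candidates()
  report <- list()
  for (it in seq_len(max_iter)) {
    cand <- discover_novel_j(rearr, gset, min_freq = min_freq, strain = strain)
    cand <- cand[!cand$sequence %in% gset$sequence, , drop = FALSE]
    if (nrow(cand) == 0L) {
      report[[it]] <- data.frame(iteration = it, new_candidates = 0L,
                                 j_changed = 0L,
                                 no_j = sum(rearr$j_call == ""))
      break
    }
    gset <- germline_set(
      name = c(gset$name, cand$name),
      sequence = c(gset$sequence, cand$sequence),
      segment = c(gset$segment, rep("J", nrow(cand))),
      locus = attr(gset, "locus"), strain = attr(gset, "strain"),
      status = c(gset$status, rep("inferred-novel", nrow(cand))))
    new_rearr <- assign_segments(records, gset, ignore_j = TRUE)
    report[[it]] <- data.frame(
      iteration = it, new_candidates = nrow(cand),
      j_changed = sum(new_rearr$j_call != rearr$j_call),
      no_j = sum(new_rearr$j_call == ""))
    rearr <- new_rearr
    all_cand <- rbind(all_cand, cand)
  }
  list(gset = gset, rearrangements = rearr, candidates = all_cand,
       report = do.call(rbind, report))
}
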