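# Per-strain germline V inference from assigned rearrangements: clonal
# threshold estimation, clone grouping, identity-stratified greedy
# clustering with polymorphic-position splitting, consensus derivation with
# the 0.1% clone-support rule, and genotype-style validation.

#' Estimate the clonal distance threshold for one sample
#'
#' Computes each rearrangement's normalized Hamming distance to its nearest
#' neighbour among rearrangements with the same V call and junction length,
#' then takes the deepest valley of a kernel density estimate between the
#' first two modes. When the distribution is unimodal, degenerate, or there
#' are fewer than `min_n` rearrangements, the conventional fallback of 0.1
#' is returned with a warning.
#'
#' @param rearr a rearrangement table with `j_region` junctions.
#' @param min_n minimum number of rearrangements for estimation.
#' @param fallback threshold used when no valley can be located.
#' @return a single distance threshold in `[0, 1]`.
#' @export
estimate_clone_threshold <- function(rearr, min_n = 50L, fallback = 0.1) {
  if (nrow(rearr) < min_n) {
    warning("fewer than ", min_n, " rearrangements; using fallback threshold ",
            fallback)
    return(fallback)
  }
  d <- nearest_junction_distances(rearr)
  d <- d[is.finite(d)]
  if (length(d) < 2L || all(d == d[1])) {
    warning("junction distances are degenerate; using fallback threshold ",
            fallback)
    return(fallback)
  }
  dens <- stats::density(d, from = 0, to = max(d), n = 512)
  thr <- .density_valley(dens$x, dens$y)
  if (is.na(thr)) {
    warning("junction distance distribution is unimodal; using fallback ",
            "threshold ", fallback)
    return(fallback)
  }
  thr
}

#' Nearest-neighbour junction distances
#'
#' Normalized Hamming distance from each rearrangement's junction to its
#' nearest neighbour within the same (V call, junction length) partition;
#' `Inf` for rearrangements with no partner.
#'
#' @param rearr a rearrangement table.
#' @return numeric vector aligned with the rows of `rearr`.
#' @export
nearest_junction_distances <- function(rearr) {
  out <- rep(Inf, nrow(rearr))
  key <- paste(rearr$v_call, nchar(rearr$j_region), sep = "\r")
  for (ix in split(seq_len(nrow(rearr)), key)) {
    if (length(ix) < 2L) next
    len <- nchar(rearr$j_region[ix[1]])
    if (len == 0L) { out[ix] <- 0; next }
    dm <- cpp_hamming_matrix(rearr$j_region[ix]) / len
    diag(dm) <- Inf
    out[ix] <- apply(dm, 1L, min)
  }
  out
}

# deepest valley of a density curve between its first two local maxima
.density_valley <- function(x, y) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  # treat a high boundary at 0 as the first mode
  if (y[1] > y[2]) is_max[1] <- TRUE
  peaks <- which(is_max)
  # ignore negligible ripples
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (length(peaks) < 2L) return(NA_real_)
  lo <- peaks[1]; hi <- peaks[2]
  x[lo + which.min(y[(lo + 1):(hi - 1)])]
}

#' Group rearrangements into clones
#'
#' Single-linkage clustering of junction sequences within each
#' (V call, junction length) partition at the given normalized Hamming
#' threshold. Clone ids are deterministic: clones are ordered by their
#' smallest member `sequence_id`.
#'
#' For each clone a representative V profile is built by per-position
#' majority over the members' profiles (see [assign_segments()]).
#'
#' @param rearr a rearrangement table carrying the `v_profiles` attribute.
#' @param threshold normalized Hamming distance threshold in `[0, 1]`.
#' @return a list of class `clone_set`: `clones` (data.frame with clone_id,
#'   v_call, v_identity, n_members, dupcount), `profiles` (list of
#'   representative profiles), and `rearrangements` (input with `clone_id`
#'   filled).
#' @export
group_clones <- function(rearr, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  profiles <- attr(rearr, "v_profiles")
  if (is.null(profiles)) stop("rearrangements must carry the v_profiles attribute ",
                              "(produced by assign_segments)")
  n <- nrow(rearr)
  member <- integer(n)
  key <- paste(rearr$v_call, nchar(rearr$j_region), sep = "\r")
  next_id <- 0L
  for (ix in split(seq_len(n), key)) {
    if (length(ix) == 1L) {
      next_id <- next_id + 1L
      member[ix] <- next_id
      next
    }
    len <- nchar(rearr$j_region[ix[1]])
    cl <- if (len == 0L) rep(1L, length(ix)) else {
      dm <- cpp_hamming_matrix(rearr$j_region[ix]) / len
      hc <- stats::hclust(stats::as.dist(dm), method = "single")
      stats::cutree(hc, h = threshold)
    }
    member[ix] <- next_id + cl
    next_id <- next_id + max(cl)
  }
  # deterministic clone ids ordered by smallest member sequence_id
  min_id <- vapply(split(rearr$sequence_id, member), function(s) sort(s)[1], "")
  ord <- order(min_id)
  relabel <- setNames(seq_along(ord), names(min_id)[ord])
  clone_idx <- relabel[as.character(member)]
  rearr$clone_id <- sprintf("clone_%05d", clone_idx)

  groups <- split(seq_len(n), rearr$clone_id)
  reps <- lapply(groups, function(ix) .clone_representative(profiles[ix]))
  clones <- data.frame(
    clone_id = names(groups),
    v_call = vapply(groups, function(ix) rearr$v_call[ix[1]], ""),
    v_identity = vapply(groups, function(ix)
      stats::median(rearr$v_identity[ix]), 0),
    n_members = lengths(groups),
    dupcount = vapply(groups, function(ix) sum(rearr$dupcount[ix]), 0),
    stringsAsFactors = FALSE)
  rownames(clones) <- NULL
  structure(list(clones = clones, profiles = reps, rearrangements = rearr),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("Clone set:", nrow(x$clones), "clones over",
      length(unique(x$clones$v_call)), "V calls\n")
  invisible(x)
}

# majority-vote representative over member profiles; shadow weights are the
# mean member weights for the last JUNCTION_SHADOW allele positions
.clone_representative <- function(profs) {
  L <- length(profs[[1]]$bases)
  shadow_p <- seq.int(max(1L, L - JUNCTION_SHADOW + 1L), L)
  if (length(profs) == 1L) {
    p <- profs[[1]]
    w <- vapply(L - shadow_p, function(k) .shadow_weight(p$delta, k), 0)
    return(list(bases = p$bases, wtail = setNames(w, shadow_p), covered = p$covered))
  }
  mat <- vapply(profs, function(p) p$bases, character(L))
  bases <- apply(mat, 1L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
  w <- vapply(L - shadow_p, function(k)
    mean(vapply(profs, function(p) .shadow_weight(p$delta, k), 0)), 0)
  list(bases = bases, wtail = setNames(w, shadow_p),
       covered = sum(!is.na(bases)))
}

#' Infer germline V alleles from clones
#'
#' Clone representatives are grouped by (V call, percent-identity stratum),
#' clustered greedily within each group (a clone joins the first cluster
#' whose seed it matches at `cluster_identity` over their common covered
#' positions; seeds are taken in order of decreasing read support), split
#' recursively at strongly polymorphic positions (minority base carried by
#' at least `split_min` clones and `split_minority` of voters -- this is
#' what separates co-alleles differing by as little as one nucleotide), and
#' reduced to a per-position majority consensus. The junction-shadow
#' positions (last 3 nt of the V) are decided by a vote weighted by each
#' member's probability of genuinely covering the position. Clusters
#' supported by fewer than `min_support` of all clones in the strain (or
#' fewer than `min_clones` clones) are discarded; identical consensus
#' sequences arising in different groups are merged, sequences that are
#' substrings of longer candidates are folded into them, and candidates
#' identical except within the junction shadow are re-voted over their
#' pooled membership.
#'
#' @param clones a `clone_set` from [group_clones()].
#' @param reference a [germline_set()] of starting reference V alleles.
#' @param min_support minimal clone support fraction (the 0.1% rule).
#' @param min_clones absolute minimal clone count per retained cluster.
#' @param cluster_identity greedy clustering identity threshold.
#' @param stratum_width width of the percent-identity strata.
#' @param split_minority,split_min minority fraction and absolute count
#'   required to split a cluster at a polymorphic position.
#' @return a data.frame of class `inferred_alleles` with columns `name`,
#'   `sequence`, `n_clones`, `support_fraction`, `nearest_reference`,
#'   `nearest_identity`, `status`.
#' @export
infer_v_germline <- function(clones, reference, min_support = 0.001,
                             min_clones = 5L, cluster_identity = 0.94,
                             stratum_width = 2.5, split_minority = 0.2,
                             split_min = 5L) {
  stopifnot(inherits(clones, "clone_set"))
  cl <- clones$clones
  if (nrow(cl) == 0L) stop("empty clone set")
  refs <- reference[reference$segment == "V", , drop = FALSE]
  N <- nrow(cl)
  min_n <- max(min_clones, ceiling(min_support * N))

  stratum <- round(cl$v_identity / stratum_width)
  key <- paste(cl$v_call, stratum, sep = "\r")
  clusters <- list()   # each: list(idx = clone row indices)
  for (g in split(seq_len(N), key)) {
    ord <- g[order(-cl$dupcount[g], -vapply(clones$profiles[g], `[[`, 0, "covered"),
                   cl$clone_id[g])]
    seeds <- integer(0)
    assign <- vector("list", 0)
    for (i in ord) {
      placed <- FALSE
      for (s in seq_along(seeds)) {
        idn <- .profile_identity(clones$profiles[[i]]$bases,
                                 clones$profiles[[seeds[s]]]$bases)
        if (!is.na(idn) && idn >= cluster_identity) {
          assign[[s]] <- c(assign[[s]], i); placed <- TRUE; break
        }
      }
      if (!placed) { seeds <- c(seeds, i); assign[[length(seeds)]] <- i }
    }
    clusters <- c(clusters, assign)
  }

  # recursive polymorphic-position splitting
  founder_of <- function(idx) {
    vc <- cl$v_call[idx[1]]
    refs$sequence[match(vc, refs$name)]
  }
  final <- list()
  splitq <- clusters
  while (length(splitq)) {
    idx <- splitq[[1]]; splitq <- splitq[-1]
    sp <- .find_split(clones$profiles[idx], split_minority, split_min)
    if (is.null(sp)) { final <- c(final, list(idx)); next }
    bases <- vapply(clones$profiles[idx], function(p) p$bases[sp], "")
    parts <- split(idx, factor(bases, exclude = NULL))
    # members with NA at the split position follow the largest part
    na_part <- which(is.na(names(parts)) | names(parts) == "NA")
    if (length(na_part)) {
      sizes <- lengths(parts[-na_part])
      if (length(sizes)) {
        big <- which.max(sizes)
        parts[-na_part][[big]] <- sort(c(parts[-na_part][[big]], parts[[na_part]]))
        parts <- parts[-na_part]
      }
    }
    splitq <- c(splitq, unname(parts))
  }

  # consensus + support filter
  cand <- list()
  for (idx in final) {
    if (length(idx) < min_n) next
    fseq <- founder_of(idx)
    cons <- .cluster_consensus(clones$profiles[idx], fseq)
    if (is.null(cons)) next
    cand[[length(cand) + 1L]] <- list(sequence = cons, idx = idx)
  }
  if (!length(cand)) {
    return(.empty_inferred())
  }

  # exact dedup, substring folding, junction-shadow arbitration
  cand <- .dedup_candidates(cand, clones$profiles)

  .annotate_inferred(vapply(cand, `[[`, "", "sequence"),
                     vapply(cand, function(x) length(x$idx), 0L),
                     refs, total_clones = N)
}

# annotate candidate sequences against the reference and assemble the
# inferred_alleles data.frame
.annotate_inferred <- function(seqs, n_clones, refs, total_clones) {
  near <- .nearest_reference(seqs, refs)
  status <- ifelse(seqs %in% refs$sequence, "inferred-known", "inferred-novel")
  name <- character(length(seqs))
  known <- status == "inferred-known"
  name[known] <- refs$name[match(seqs[known], refs$sequence)]
  # provisional names for novel alleles: nearest reference + _S<k>
  cnt <- integer(0)
  for (i in which(!known)) {
    base <- near$name[i]
    k <- if (base %in% names(cnt)) cnt[[base]] + 1L else 1L
    cnt[base] <- k
    name[i] <- sprintf("%s_S%d", base, k)
  }
  out <- data.frame(name = name, sequence = seqs, n_clones = n_clones,
                    support_fraction = n_clones / total_clones,
                    nearest_reference = near$name,
                    nearest_identity = near$identity,
                    status = status, stringsAsFactors = FALSE)
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_clones") <- total_clones
  class(out) <- c("inferred_alleles", "data.frame")
  out
}

.empty_inferred <- function() {
  out <- data.frame(name = character(), sequence = character(),
                    n_clones = integer(), support_fraction = numeric(),
                    nearest_reference = character(),
                    nearest_identity = numeric(), status = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("inferred_alleles", "data.frame")
  out
}

#' @export
print.inferred_alleles <- function(x, ...) {
  cat("Inferred V alleles:", nrow(x), "(",
      sum(x$status == "inferred-novel"), "novel )\n")
  print.data.frame(as.data.frame(x)[, c("name", "n_clones", "support_fraction",
                                        "nearest_identity", "status")])
  invisible(x)
}

# identity between two profiles over common covered positions
.profile_identity <- function(a, b, min_common = 50L) {
  common <- !is.na(a) & !is.na(b)
  nc <- sum(common)
  if (nc < min_common) return(NA_real_)
  sum(a[common] == b[common]) / nc
}

# most polymorphic interior position qualifying for a split, or NULL
.find_split <- function(profs, split_minority, split_min) {
  if (length(profs) < 2L * split_min) return(NULL)
  L <- length(profs[[1]]$bases)
  interior <- seq_len(max(0L, L - JUNCTION_SHADOW))
  mat <- vapply(profs, function(p) p$bases, character(L))
  best <- NULL; best_frac <- 0
  for (p in interior) {
    col <- mat[p, ]
    col <- col[!is.na(col)]
    if (length(col) < 2L * split_min) next
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) < 2L) next
    minority <- sum(tb[-1])
    frac <- minority / length(col)
    if (tb[2] >= split_min && frac >= split_minority && frac > best_frac) {
      best <- p; best_frac <- frac
    }
  }
  best
}

# per-position consensus over member profiles; founder-polarized tie-break
# at interior positions, weighted vote in the junction shadow
.cluster_consensus <- function(profs, founder_seq) {
  L <- length(profs[[1]]$bases)
  fb <- if (!is.null(founder_seq) && !is.na(founder_seq) &&
            nchar(founder_seq) == L) strsplit(founder_seq, "")[[1]]
  else rep(NA_character_, L)
  mat <- vapply(profs, function(p) p$bases, character(L))
  shadow_from <- L - JUNCTION_SHADOW + 1L
  cons <- rep(NA_character_, L)
  for (p in seq_len(L)) {
    col <- mat[p, ]
    if (p >= shadow_from) {
      w <- vapply(profs, function(pr) {
        wi <- pr$wtail[as.character(p)]
        if (length(wi) != 1L || is.na(wi)) 0 else unname(wi)
      }, 0)
      ok <- !is.na(col)
      if (any(ok) && sum(w[ok]) > 0) {
        votes <- tapply(w[ok], col[ok], sum)
      } else if (any(ok)) {
        votes <- table(col[ok])
      } else next
    } else {
      ok <- !is.na(col)
      if (!any(ok)) next
      votes <- table(col[ok])
    }
    mx <- max(votes)
    top <- sort(names(votes)[votes == mx])
    cons[p] <- if (length(top) > 1L && !is.na(fb[p]) && fb[p] %in% top) fb[p]
    else top[1]
  }
  cov <- which(!is.na(cons))
  if (!length(cov)) return(NULL)
  rng <- seq.int(min(cov), max(cov))
  if (anyNA(cons[rng])) return(NULL)   # interior hole: unusable cluster
  paste(cons[rng], collapse = "")
}

.dedup_candidates <- function(cand, profiles) {
  # exact merges
  seqs <- vapply(cand, `[[`, "", "sequence")
  merged <- list()
  for (i in seq_along(cand)) {
    hit <- match(cand[[i]]$sequence, vapply(merged, `[[`, "", "sequence"))
    if (!is.na(hit)) merged[[hit]]$idx <- sort(unique(c(merged[[hit]]$idx, cand[[i]]$idx)))
    else merged[[length(merged) + 1L]] <- cand[[i]]
  }
  # fold strict substrings into their superstring
  keep <- rep(TRUE, length(merged))
  seqs <- vapply(merged, `[[`, "", "sequence")
  ord <- order(-nchar(seqs))
  for (i in ord) {
    if (!keep[i]) next
    for (k in seq_along(merged)) {
      if (k == i || !keep[k]) next
      if (nchar(seqs[k]) < nchar(seqs[i]) && grepl(seqs[k], seqs[i], fixed = TRUE)) {
        merged[[i]]$idx <- sort(unique(c(merged[[i]]$idx, merged[[k]]$idx)))
        keep[k] <- FALSE
      }
    }
  }
  merged <- merged[keep]
  # junction-shadow arbitration: candidates equal outside the shadow are
  # re-voted over their pooled membership
  seqs <- vapply(merged, `[[`, "", "sequence")
  stem <- paste(substr(seqs, 1L, nchar(seqs) - JUNCTION_SHADOW), nchar(seqs))
  out <- list()
  for (g in split(seq_along(merged), stem)) {
    if (length(g) == 1L) { out <- c(out, merged[g]); next }
    idx <- sort(unique(unlist(lapply(merged[g], `[[`, "idx"))))
    cons <- .cluster_consensus(profiles[idx], NA_character_)
    if (is.null(cons)) cons <- merged[[g[1]]]$sequence
    out[[length(out) + 1L]] <- list(sequence = cons, idx = idx)
  }
  ord <- order(vapply(out, `[[`, "", "sequence"))
  out[ord]
}

.nearest_reference <- function(seqs, refs) {
  name <- character(length(seqs)); ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    ids <- vapply(refs$sequence, function(r)
      align(seqs[i], r, mode = "global")$percent_identity, 0)
    best <- which(ids == max(ids))
    best <- best[order(refs$name[best])][1]
    name[i] <- refs$name[best]; ident[i] <- ids[best]
  }
  list(name = name, identity = ident)
}

#' Polish inferred alleles against the full read evidence
#'
#' Cluster consensus sequences are accurate in their interior but the last
#' few V positions sit in the junction shadow, where 3'-trimmed molecules
#' contribute junction-derived bases. This step re-assigns the complete
#' collapsed read set (including dupcount-1 records excluded from clonal
#' inference) to the inferred candidates and
#' (1) re-votes every candidate's junction-shadow positions with the
#' pooled, trim-probability-weighted, dupcount-weighted read evidence, and
#' (2) drops candidates whose dupcount-weighted read support falls below
#' `min_read_fraction` (the read-level analogue of the clone support rule;
#' consensus artifacts only attract the few reads that share their private
#' mutation). Identical sequences arising from the re-vote are merged and
#' the result is re-annotated against the starting reference.
#'
#' @param inferred an `inferred_alleles` data.frame.
#' @param records collapsed reads before the dupcount filter.
#' @param reference the starting reference [germline_set()] (V used for
#'   annotation, J used to locate junctions).
#' @param min_read_fraction read-support threshold for retaining a
#'   candidate.
#' @return a polished `inferred_alleles` data.frame.
#' @export
polish_inferred <- function(inferred, records, reference,
                            min_read_fraction = 0.001) {
  if (nrow(inferred) == 0L) return(inferred)
  cand_set <- germline_set(inferred$name, inferred$sequence, segment = "V",
                           locus = attr(reference, "locus"),
                           status = "inferred-novel")
  jref <- reference[reference$segment == "J", , drop = FALSE]
  gset <- germline_set(c(cand_set$name, jref$name),
                       c(cand_set$sequence, jref$sequence),
                       segment = c(cand_set$segment, jref$segment),
                       locus = attr(reference, "locus"))
  rearr <- assign_segments(records, gset, ignore_j = TRUE)
  profs <- attr(rearr, "v_profiles")
  total_w <- sum(rearr$dupcount)
  seqs <- character(nrow(inferred))
  support <- numeric(nrow(inferred))
  for (i in seq_len(nrow(inferred))) {
    nm <- inferred$name[i]
    s <- inferred$sequence[i]
    ix <- which(rearr$v_call == nm)
    support[i] <- sum(rearr$dupcount[ix]) / total_w
    if (!length(ix)) { seqs[i] <- s; next }
    L <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    for (p in seq.int(max(1L, L - JUNCTION_SHADOW + 1L), L)) {
      votes <- numeric(0)
      for (k in ix) {
        b <- profs[[k]]$bases[p]
        if (is.na(b)) next
        w <- .shadow_weight(profs[[k]]$delta, L - p) * rearr$dupcount[k]
        if (w <= 0) next
        votes[b] <- (if (b %in% names(votes)) votes[[b]] else 0) + w
      }
      if (!length(votes)) next
      mx <- max(votes)
      top <- sort(names(votes)[votes == mx])
      ch[p] <- if (ch[p] %in% top) ch[p] else top[1]
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  keep <- support >= min_read_fraction
  seqs <- seqs[keep]
  n_clones <- inferred$n_clones[keep]
  if (!length(seqs)) return(.empty_inferred())
  # merge candidates that became identical
  agg <- rowsum(n_clones, seqs)
  cand <- lapply(seq_len(nrow(agg)), function(i)
    list(sequence = rownames(agg)[i], n = agg[i, 1]))
  N <- attr(inferred, "total_clones")
  if (is.null(N)) N <- sum(inferred$n_clones)
  .annotate_inferred(vapply(cand, `[[`, "", "sequence"),
                     vapply(cand, `[[`, 0, "n"),
                     reference[reference$segment == "V", , drop = FALSE],
                     total_clones = N)
}

#' Genotype-style validation of inferred alleles
#'
#' Re-assigns reads against the inferred allele set and retains an allele
#' only if at least `min_exact` reads align to it at 100% V identity with
#' that allele as their unique best hit. This strict confirmation step is
#' suited to deep data or lightly mutated repertoires; under substantial
#' SHM, exact-match supporters become rare and validation is better applied
#' with a lower `min_exact` or skipped.
#'
#' @param inferred an `inferred_alleles` data.frame.
#' @param records collapsed reads (sequence-record table).
#' @param min_exact minimum number of uniquely exact supporting reads.
#' @return list with `validated` (subset of `inferred`), `removed` (names)
#'   and `support` (named exact-support counts).
#' @export
validate_genotype <- function(inferred, records, min_exact = 3L) {
  if (nrow(inferred) == 0L)
    return(list(validated = inferred, removed = character(), support = integer()))
  support <- setNames(integer(nrow(inferred)), inferred$name)
  for (i in seq_len(nrow(records))) {
    read <- records$sequence[i]
    scores <- align_scores(inferred$sequence, read, mode = "glocal")
    mx <- which(scores == max(scores))
    if (length(mx) != 1L) next                       # ambiguous best hit
    aln <- align(inferred$sequence[mx], read, mode = "glocal")
    prof <- .v_profile(aln, inferred$sequence[mx], read, NA_integer_)
    if (!is.na(prof$identity) && prof$identity == 100)
      support[mx] <- support[mx] + 1L
  }
  keep <- support >= min_exact
  list(validated = inferred[keep, , drop = FALSE],
       removed = inferred$name[!keep],
       support = support)
}

#' Convert inferred alleles to a germline set
#' @param inferred an `inferred_alleles` data.frame.
#' @param strain,locus labels for the resulting set.
#' @export
as_germline_set <- function(inferred, strain = NA_character_, locus = "IGK") {
  germline_set(inferred$name, inferred$sequence, segment = "V", locus = locus,
               strain = strain, status = inferred$status)
}
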