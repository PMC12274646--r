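# Comparison of inferred germline sets against a reference allele database
# and between strains: presence/identity summaries, exact-sequence sharing
# sets (UpSet-style data), best-match mean-identity matrices with a minimum
# alignment length rule, and average-linkage hierarchical clustering.

#' Representation of a germline set in a reference database
#'
#' For each allele the best reference match by percent identity (glocal:
#' query global, reference local). An allele is "present" only when it
#' matches a reference at 100% identity over the full query -- any
#' mismatch counts as absent/undocumented.
#'
#' @param gset a [germline_set()] (V alleles are compared).
#' @param reference_db a [germline_set()] acting as the database.
#' @return data.frame: `name`, `best_match`, `percent_identity`, `present`.
#' @export
db_representation <- function(gset, reference_db) {
  q <- gset[gset$segment == "V", , drop = FALSE]
  r <- reference_db[reference_db$segment == "V", , drop = FALSE]
  if (nrow(r) == 0L) stop("reference database is empty")
  best_name <- character(nrow(q)); best_id <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    exact <- which(r$sequence == q$sequence[i])
    if (length(exact)) {
      best <- exact[order(r$name[exact])][1]
      best_name[i] <- r$name[best]; best_id[i] <- 100
      next
    }
    ids <- vapply(r$sequence, function(s)
      align(q$sequence[i], s, mode = "glocal")$percent_identity, 0)
    best <- which(ids == max(ids))
    best <- best[order(r$name[best])][1]
    best_name[i] <- r$name[best]; best_id[i] <- ids[best]
  }
  data.frame(name = q$name, best_match = best_name,
             percent_identity = best_id,
             present = best_id == 100 & q$sequence %in% r$sequence,
             stringsAsFactors = FALSE)
}

#' Exact-sequence sharing sets across strains
#'
#' Groups the unique allele sequences across all sets by the exact set of
#' strains carrying them (the data behind an UpSet plot). Combinations are
#' ordered by count (desc), then lexicographic strain tuple.
#'
#' @param gsets named list of [germline_set()] objects (>= 2 strains).
#' @param segment segment to compare (default `"V"`).
#' @return list of class `sharing_report`: `memberships` (data.frame
#'   sequence/strains), `combinations` (data.frame strains/count),
#'   `per_strain` (named set sizes).
#' @export
sharing_sets <- function(gsets, segment = "V") {
  if (length(gsets) < 2L) stop("at least two strains are required")
  if (is.null(names(gsets)) || any(!nzchar(names(gsets))))
    stop("gsets must be a named list of germline sets")
  seqs <- lapply(gsets, function(g) unique(g$sequence[g$segment == segment]))
  uniq <- sort(unique(unlist(seqs)))
  member <- vapply(names(gsets), function(s) uniq %in% seqs[[s]],
                   logical(length(uniq)))
  if (length(uniq) == 1L) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(gsets)))
  combo <- apply(member, 1L, function(row)
    paste(sort(names(gsets)[row]), collapse = "+"))
  tab <- table(combo)
  combinations <- data.frame(strains = names(tab), count = as.integer(tab),
                             stringsAsFactors = FALSE)
  combinations <- combinations[order(-combinations$count, combinations$strains), ,
                               drop = FALSE]
  rownames(combinations) <- NULL
  structure(list(
    memberships = data.frame(sequence = uniq, strains = combo,
                             stringsAsFactors = FALSE),
    combinations = combinations,
    per_strain = vapply(seqs, length, 0L)),
    class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat("Sharing report:", nrow(x$memberships), "unique sequences across",
      length(x$per_strain), "strains\n")
  print.data.frame(utils::head(x$combinations, 10))
  invisible(x)
}

#' Mean best-match identity between two germline sets
#'
#' The smaller set is the query (ties resolve to the lexicographically
#' first strain name). Each query allele is aligned glocally (query global
#' within the subject allele, mirroring how a short query matches inside a
#' longer target) and the best match in the other set is chosen by percent
#' identity, then alignment length, then name;
#' matches whose aligned length (columns excluding terminal gaps) is below
#' `min_alignment_length` are excluded. The mean identity over query
#' alleles with a qualifying match is returned.
#'
#' @param set_a,set_b [germline_set()] objects (V alleles compared).
#' @param min_alignment_length minimal aligned length in nt.
#' @return list: `mean_identity`, `n_query`, `n_excluded`, `query_strain`.
#' @export
pairwise_set_similarity <- function(set_a, set_b, min_alignment_length = 275L) {
  a <- set_a[set_a$segment == "V", , drop = FALSE]
  b <- set_b[set_b$segment == "V", , drop = FALSE]
  if (nrow(a) == 0L && nrow(b) == 0L) stop("both germline sets are empty")
  sa <- attr(set_a, "strain"); sb <- attr(set_b, "strain")
  if (is.na(sa)) sa <- "A"
  if (is.na(sb)) sb <- "B"
  swap <- nrow(b) < nrow(a) ||
    (nrow(b) == nrow(a) && order(c(sa, sb))[1] == 2L)
  if (swap) { tmp <- a; a <- b; b <- tmp; qs <- sb } else qs <- sa
  ids <- numeric(0); n_excl <- 0L
  for (i in seq_len(nrow(a))) {
    best_id <- -1; best_len <- -1L; best_nm <- ""
    for (k in seq_len(nrow(b))) {
      al <- align(a$sequence[i], b$sequence[k], mode = "glocal")
      len <- al$columns
      id <- al$percent_identity
      if (len < min_alignment_length) next
      if (id > best_id || (id == best_id && (len > best_len ||
          (len == best_len && b$name[k] < best_nm)))) {
        best_id <- id; best_len <- len; best_nm <- b$name[k]
      }
    }
    if (best_id < 0) n_excl <- n_excl + 1L else ids <- c(ids, best_id)
  }
  list(mean_identity = if (length(ids)) mean(ids) else NA_real_,
       n_query = nrow(a), n_excluded = n_excl, query_strain = qs)
}

#' Similarity matrix and hierarchical clustering of strains
#'
#' Builds the symmetric strain-by-strain matrix of mean best-match
#' identities (diagonal 100) and clusters strains by average linkage on
#' `100 - similarity`.
#'
#' @param gsets named list of [germline_set()] objects.
#' @inheritParams pairwise_set_similarity
#' @return list of class `similarity_result`: `matrix`, `hclust`,
#'   `newick` (dendrogram as a Newick string), `leaf_order`.
#' @export
similarity_matrix_and_clustering <- function(gsets,
                                             min_alignment_length = 275L) {
  if (length(gsets) < 2L) stop("at least two strains are required")
  strains <- sort(names(gsets))
  n <- length(strains)
  m <- matrix(100, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1L)) {
    for (k in seq.int(i + 1L, n)) {
      sim <- pairwise_set_similarity(gsets[[strains[i]]], gsets[[strains[k]]],
                                     min_alignment_length)
      m[i, k] <- m[k, i] <- sim$mean_identity
    }
  }
  hc <- stats::hclust(stats::as.dist(100 - m), method = "average")
  tree <- ape::as.phylo(hc)
  list(matrix = m, hclust = hc,
       newick = ape::write.tree(tree),
       leaf_order = hc$labels[hc$order]) |>
    structure(class = "similarity_result")
}

#' Format a count as the percentage a report would print
#'
#' `pct_label(311, 459, 1)` gives `"67.8%"`; with `digits = 0`,
#' `pct_label(74, 324)` gives `"23%"`.
#'
#' @param n,total numerator and denominator.
#' @param digits decimal places.
#' @return character scalar like `"67.8%"`.
#' @export
pct_label <- function(n, total, digits = 0L) {
  sprintf(paste0("%.", digits, "f%%"), round(100 * n / total, digits))
}
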