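# Evolutionary analysis of V genes: translation with stop-codon filtering,
# mean pairwise amino-acid identities, NJ trees on identity distances,
# extraction of family subtrees of bounded height, and per-gene divergence
# from the subtree consensus.

#' Translate V genes and discard stop-codon sequences
#'
#' Standard-code translation in the configured frame; the trailing partial
#' codon is dropped. Sequences whose translation contains a stop codon
#' (internal or terminal) are discarded, as are sequences shorter than one
#' codon.
#'
#' @param gset a [germline_set()] or data.frame with `name` and `sequence`.
#' @param frame 0-based reading frame offset (0, 1 or 2).
#' @return list: `aa` (named character vector of amino-acid sequences) and
#'   `discarded` (data.frame name/reason).
#' @export
translate_and_filter <- function(gset, frame = 0L) {
  stopifnot(frame %in% 0:2)
  v <- as.data.frame(gset)
  if ("segment" %in% names(v)) v <- v[v$segment == "V", , drop = FALSE]
  aa <- character(0)
  disc <- list()
  for (i in seq_len(nrow(v))) {
    s <- substr(v$sequence[i], frame + 1L, nchar(v$sequence[i]))
    ncod <- nchar(s) %/% 3L
    if (ncod < 1L) {
      disc[[length(disc) + 1L]] <- data.frame(name = v$name[i],
                                              reason = "shorter than one codon")
      next
    }
    s <- substr(s, 1L, 3L * ncod)
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    if (grepl("*", p, fixed = TRUE)) {
      disc[[length(disc) + 1L]] <- data.frame(name = v$name[i],
                                              reason = "stop codon")
      next
    }
    aa[v$name[i]] <- p
  }
  list(aa = aa,
       discarded = if (length(disc)) do.call(rbind, disc)
       else data.frame(name = character(), reason = character()))
}

#' Mean pairwise amino-acid identity per gene
#'
#' Global pairwise alignments between all genes of a group; each gene's
#' value is its mean percent identity against all other genes in the
#' group. With `pairs = TRUE` the grouping is interpreted as strains and
#' identities are computed for cross-strain pairs only.
#'
#' @param aa named character vector of amino-acid sequences.
#' @param grouping factor/character aligned with `aa` (e.g. strain or
#'   locus); `NULL` treats all sequences as one group.
#' @param pairs compute per strain-pair summaries instead of per-gene
#'   within-group means.
#' @return with `pairs = FALSE`: data.frame `name`, `group`,
#'   `mean_identity` (NA for singleton groups) plus attribute `summary`
#'   (per-group median and quartiles). With `pairs = TRUE`: data.frame
#'   `group_a`, `group_b`, `median_identity`, `mean_identity`, `n_pairs`.
#' @export
mean_pairwise_identity <- function(aa, grouping = NULL, pairs = FALSE) {
  if (is.null(grouping)) grouping <- rep("all", length(aa))
  grouping <- as.character(grouping)
  if (!pairs) {
    out <- list()
    for (g in sort(unique(grouping))) {
      ix <- which(grouping == g)
      if (length(ix) == 1L) {
        out[[g]] <- data.frame(name = names(aa)[ix], group = g,
                               mean_identity = NA_real_)
        next
      }
      idm <- .aa_identity_matrix(aa[ix])
      mi <- (rowSums(idm) - 100) / (length(ix) - 1L)
      out[[g]] <- data.frame(name = names(aa)[ix], group = g,
                             mean_identity = unname(mi))
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    ok <- !is.na(res$mean_identity)
    summ <- do.call(rbind, lapply(split(res$mean_identity[ok], res$group[ok]),
                                  function(x) data.frame(
                                    median = stats::median(x),
                                    q1 = unname(stats::quantile(x, 0.25)),
                                    q3 = unname(stats::quantile(x, 0.75)))))
    attr(res, "summary") <- summ
    return(res)
  }
  gs <- sort(unique(grouping))
  rows <- list()
  for (i in seq_along(gs)) {
    for (k in seq.int(i, length(gs))) {
      if (i == k) next
      ia <- which(grouping == gs[i]); ib <- which(grouping == gs[k])
      ids <- numeric(0)
      for (a in ia) for (b in ib)
        ids <- c(ids, .aa_identity(aa[[a]], aa[[b]]))
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gs[i], group_b = gs[k],
        median_identity = stats::median(ids), mean_identity = mean(ids),
        n_pairs = length(ids))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.aa_identity <- function(a, b) {
  align(a, b, mode = "global", n_wildcard = FALSE,
        check_alphabet = FALSE)$percent_identity
}

# row gene is the alignment query; for dissimilar sequences the identity can
# differ slightly with direction, so the matrix is not forced symmetric here
.aa_identity_matrix <- function(aa) {
  n <- length(aa)
  m <- matrix(100, n, n, dimnames = list(names(aa), names(aa)))
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      m[i, k] <- .aa_identity(aa[[i]], aa[[k]])
    }
  }
  m
}

#' Build an amino-acid NJ tree, midpoint rooted
#'
#' Pairwise global alignment identities define distances
#' `1 - identity/100`; the neighbor-joining tree is midpoint rooted
#' (via phangorn) so the tree height `L` is well defined.
#'
#' @param aa named character vector of amino-acid sequences (>= 3, unique
#'   names).
#' @return an ape `phylo` tree with attribute `height`.
#' @export
build_aa_tree <- function(aa) {
  if (length(aa) < 3L) stop("at least three sequences are required")
  if (anyDuplicated(names(aa))) stop("duplicate sequence labels")
  d <- (100 - .aa_identity_matrix(aa)) / 100
  d <- (d + t(d)) / 2      # identities are direction-averaged for the tree
  tree <- neighbor_joining(d)
  if (sum(tree$edge.length) > 0) tree <- phangorn::midpoint(tree)
  attr(tree, "height") <- tree_height(tree)
  tree
}

#' Extract maximal family subtrees of bounded height
#'
#' Partitions the leaves into clusters given by the maximal subtrees whose
#' height is at most `fraction * L`, where `L` is the height of the
#' (rooted) tree. Found top-down, so every leaf lands in exactly one
#' cluster; singletons are allowed. A tree of height zero yields a single
#' cluster.
#'
#' @param tree a rooted ape `phylo` tree.
#' @param fraction height bound as a fraction of `L`, in `(0, 1]`.
#' @return list of character vectors of leaf labels.
#' @export
extract_family_subtrees <- function(tree, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- ape::Ntip(tree)
  L <- tree_height(tree)
  if (L == 0) return(list(sort(tree$tip.label)))
  bound <- fraction * L
  # subtree height per node
  nn <- n + tree$Nnode
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  height <- rep(0, nn)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    height[p] <- max(height[p], height[ch] + tree$edge.length[e])
  }
  root <- n + 1L
  clusters <- list()
  walk <- function(node) {
    if (height[node] <= bound + 1e-12) {
      tips <- if (node <= n) tree$tip.label[node]
      else ape::extract.clade(tree, node)$tip.label
      clusters[[length(clusters) + 1L]] <<- sort(tips)
      return(invisible())
    }
    for (e in children[[as.character(node)]])
      walk(tree$edge[e, 2])
  }
  walk(root)
  clusters[order(vapply(clusters, `[`, "", 1))]
}

#' Per-gene divergence from the subtree consensus
#'
#' For each cluster the member sequences are aligned (directly when equal
#' length, otherwise by star alignment against the longest member), a
#' per-column majority consensus is derived (ties resolve to the
#' alphabetically first residue), and each gene's divergence is the
#' fraction of non-matching columns in its alignment with the consensus.
#' Columns where both the gene and the consensus have a gap are excluded
#' from the denominator; a gap against a residue counts as non-matching.
#'
#' @param clusters list of character vectors of gene names (a partition of
#'   `names(aa)`).
#' @param aa named character vector of amino-acid sequences.
#' @param strains optional named vector gene -> strain label.
#' @param locus optional locus label.
#' @return data.frame of class `divergence_table`: `gene`, `strain`,
#'   `locus`, `cluster`, `divergence`.
#' @export
cluster_consensus_divergence <- function(clusters, aa, strains = NULL,
                                         locus = NA_character_) {
  if (!setequal(unlist(clusters), names(aa)))
    stop("clusters must partition the sequence names")
  if (any(lengths(clusters) == 0L)) stop("empty cluster")
  rows <- list()
  for (ci in seq_along(clusters)) {
    genes <- clusters[[ci]]
    mat <- .cluster_alignment(aa[genes])
    cons <- apply(mat, 2L, function(col) {
      tb <- table(col)
      mx <- max(tb)
      sort(names(tb)[tb == mx])[1]
    })
    for (g in genes) {
      row <- mat[g, ]
      use <- !(row == "-" & cons == "-")
      dv <- if (any(use)) mean(row[use] != cons[use]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g,
        strain = if (!is.null(strains)) unname(strains[g]) else NA_character_,
        locus = locus, cluster = ci, divergence = dv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("divergence_table", "data.frame")
  out
}

# character matrix (genes x columns) for a cluster: direct stacking for
# equal lengths, star alignment against the longest member otherwise
# (insertions relative to the centre are dropped)
.cluster_alignment <- function(aa) {
  lens <- nchar(aa)
  if (length(unique(lens)) == 1L) {
    m <- do.call(rbind, strsplit(unname(aa), ""))
    rownames(m) <- names(aa)
    return(m)
  }
  centre <- names(aa)[order(-lens, names(aa))][1]
  cl <- nchar(aa[[centre]])
  m <- matrix("-", nrow = length(aa), ncol = cl,
              dimnames = list(names(aa), NULL))
  m[centre, ] <- strsplit(aa[[centre]], "")[[1]]
  for (g in setdiff(names(aa), centre)) {
    al <- align(aa[[g]], aa[[centre]], mode = "global", n_wildcard = FALSE,
                check_alphabet = FALSE)
    qp <- al$qpos; rp <- al$rpos
    keep <- qp >= 0L & rp >= 0L        # insertions vs centre are dropped
    gch <- strsplit(aa[[g]], "")[[1]]
    m[g, rp[keep] + 1L] <- gch[qp[keep] + 1L]
  }
  m
}

#' Full divergence analysis for a set of V genes
#'
#' translate -> filter -> amino-acid NJ tree -> family subtrees of height
#' at most `fraction * L` -> per-gene divergence from subtree consensus.
#'
#' @param gset a [germline_set()] of V alleles (nucleotide).
#' @param strains optional named vector gene -> strain.
#' @param fraction subtree height bound as a fraction of the tree height.
#' @return list: `aa`, `discarded`, `tree`, `clusters`, `divergence`.
#' @export
divergence_analysis <- function(gset, strains = NULL, fraction = 0.1) {
  tr <- translate_and_filter(gset)
  if (length(tr$aa) < 3L) stop("fewer than three translatable sequences")
  tree <- build_aa_tree(tr$aa)
  clusters <- extract_family_subtrees(tree, fraction = fraction)
  div <- cluster_consensus_divergence(clusters, tr$aa, strains = strains,
                                      locus = attr(gset, "locus"))
  list(aa = tr$aa, discarded = tr$discarded, tree = tree,
       clusters = clusters, divergence = div)
}
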