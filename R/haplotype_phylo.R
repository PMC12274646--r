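# SNP-matrix masking, genotype p-distances, Saitou-Nei neighbor joining
# with deterministic tie-breaking, and haplotype group assignment by
# cutting the longest internal edges of the tree.

#' Mask positions with missing genotypes across all strains
#'
#' A position is masked whenever any strain has an `N` there, so missing
#' data can never contribute to the tree topology.
#'
#' @param gm a [genotype_matrix()].
#' @return list: `matrix` (masked [genotype_matrix()]), `masked_fraction`,
#'   `n_masked`, `n_positions`.
#' @export
mask_incomplete_positions <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  has_n <- apply(gm$genotypes == "N", 2L, any)
  mask <- gm$mask | has_n
  if (all(mask)) stop("all positions are masked; no genotype signal remains")
  list(matrix = genotype_matrix(gm$genotypes, mask),
       masked_fraction = mean(mask),
       n_masked = sum(mask), n_positions = length(mask))
}

#' Pairwise genotype p-distances over unmasked positions
#'
#' @param gm a masked [genotype_matrix()].
#' @return symmetric numeric matrix of mismatch fractions (zero diagonal).
#' @export
genotype_distance_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- !gm$mask
  if (!any(keep)) stop("no unmasked positions")
  g <- gm$genotypes[, keep, drop = FALSE]
  if (nrow(g) < 2L) stop("at least two strains are required")
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1L)) {
    for (k in seq.int(i + 1L, n)) {
      d[i, k] <- d[k, i] <- mean(g[i, ] != g[k, ])
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Canonical neighbor-joining agglomeration with deterministic behaviour:
#' ties in the Q-criterion are broken by the smallest (i, j) index pair,
#' and negative branch lengths are clamped to zero with a warning. The
#' final pair of nodes is connected through a midpoint node so the returned
#' (arbitrarily rooted) binary tree preserves all leaf-to-leaf path
#' lengths; for two taxa this yields the conventional half-length split.
#'
#' @param d symmetric distance matrix with zero diagonal and labelled rows.
#' @param tol tolerance for the symmetry check.
#' @return an ape `phylo` tree.
#' @export
neighbor_joining <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) < 2L)
    stop("d must be a square matrix with at least two taxa")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is asymmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  nodes <- labels                     # Newick fragment per active node
  act <- d
  while (nrow(act) > 2L) {
    r <- nrow(act)
    R <- rowSums(act)
    Q <- (r - 2) * act - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest (i, j) among ties, scanning column-by-row in upper triangle
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(r - 1L)) {
      for (k in seq.int(i + 1L, r)) {
        if (Q[i, k] < bq - 1e-12) { bq <- Q[i, k]; best <- c(i, k) }
      }
    }
    i <- best[1]; k <- best[2]
    li <- clamp(act[i, k] / 2 + (R[i] - R[k]) / (2 * (r - 2)))
    lk <- clamp(act[i, k] - li)
    newdist <- (act[i, ] + act[k, ] - act[i, k]) / 2
    newdist <- pmax(newdist[-c(i, k)], 0)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[k], lk)
    nodes <- c(nodes[-c(i, k)], merged)
    act <- rbind(cbind(act[-c(i, k), -c(i, k), drop = FALSE], newdist),
                 c(newdist, 0))
  }
  l <- clamp(act[1, 2] / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g);", nodes[1], l, nodes[2], l)
  if (clamped) warning("negative branch lengths clamped to zero")
  ape::read.tree(text = nwk)
}

#' Assign haplotype groups by cutting the NJ tree
#'
#' Removes the `k - 1` longest internal edges of the tree (falling back to
#' the longest terminal edges when fewer internal edges exist, which is
#' what makes `k = n` yield singleton groups) and groups leaves by the
#' resulting connected components. Groups are labelled `A`, `B`, `C`, ...
#' by descending size, then by lexicographically smallest member.
#'
#' @param x an ape `phylo` tree, or a distance matrix (a NJ tree is built).
#' @param k number of groups (1 <= k <= number of leaves).
#' @return named character vector strain -> group label.
#' @export
assign_haplotype_groups <- function(x, k) {
  tree <- if (inherits(x, "phylo")) x else neighbor_joining(x)
  n <- ape::Ntip(tree)
  if (k < 1L || k > n) stop("k must lie between 1 and the number of strains")
  edges <- tree$edge
  len <- tree$edge.length
  internal <- edges[, 2] > n
  ord <- order(!internal, -len, seq_along(len))  # internal first, longest first
  # remove edges greedily, skipping removals that do not split any leaves
  # (dropping the pendant edge of an already-isolated leaf is a no-op)
  nn <- max(edges)
  leaf_components <- function(drop) {
    parent <- seq_len(nn)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (e in seq_along(len)) {
      if (e %in% drop) next
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
    vapply(seq_len(n), find, 0L)
  }
  drop <- integer(0)
  comp <- leaf_components(drop)
  for (e in ord) {
    if (length(unique(comp)) >= k) break
    cand <- c(drop, e)
    new_comp <- leaf_components(cand)
    if (length(unique(new_comp)) > length(unique(comp))) {
      drop <- cand
      comp <- new_comp
    }
  }
  groups <- split(tree$tip.label[seq_len(n)], comp)
  sizes <- lengths(groups)
  mins <- vapply(groups, function(g) sort(g)[1], "")
  ord2 <- order(-sizes, mins)
  labels <- LETTERS[seq_along(groups)]
  out <- character(0)
  for (gi in seq_along(ord2)) {
    for (s in groups[[ord2[gi]]]) out[s] <- labels[gi]
  }
  out[sort(names(out))]
}
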