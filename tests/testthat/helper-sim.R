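# shared fixture builders (everything is generated in code)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_dna <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (h in hit) x[h] <- sample(setdiff(c("A", "C", "G", "T"), x[h]), 1)
  paste(x, collapse = "")
}

# a tiny single-strain configuration for fast end-to-end runs
tiny_config <- function(seed = 1, n_v = 6, read_depth = 2000, shm_rate = 0,
                        error_rate = 0, ...) {
  sim_config(seed = seed, haplotype_groups = list(A = "s1"), n_v = n_v,
             n_j = 3, read_depth = read_depth, shm_rate = shm_rate,
             error_rate = error_rate, dup_mean = 3, ...)
}

# germline set built directly from given sequences
gset_from <- function(seqs, segment = "V", locus = "IGK", prefix = "X",
                      strain = NA_character_) {
  germline_set(sprintf("%s%d*01", prefix, seq_along(seqs)), seqs,
               segment = segment, locus = locus, strain = strain)
}

# brute-force single linkage clustering oracle over a distance matrix
brute_single_linkage <- function(d, threshold) {
  n <- nrow(d)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (k in seq.int(i + 1, n)) {
      if (d[i, k] <= threshold && grp[i] != grp[k]) {
        grp[grp == grp[k]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# random additive distance matrix from a random tree with positive lengths
random_additive_matrix <- function(n) {
  tree <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  list(d = ape::cophenetic.phylo(tree), tree = tree)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_aa <- function(n) paste(sample(AA_ALPHABET, n, TRUE), collapse = "")

mutate_aa <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (h in hit) x[h] <- sample(setdiff(AA_ALPHABET, x[h]), 1)
  paste(x, collapse = "")
}

# two strains with V families diverged at different per-residue rates;
# returns the divergence table from the family-subtree consensus analysis
simulated_strain_divergence <- function(rate_lo, rate_hi, n_families = 6,
                                        per_family = 2, len = 60,
                                        fraction = 0.25) {
  founders <- vapply(seq_len(n_families), function(i) rand_aa(len), "")
  aa <- character(0)
  strains <- character(0)
  for (f in seq_len(n_families)) {
    for (k in seq_len(per_family)) {
      aa[sprintf("lo_f%d_%d", f, k)] <- mutate_aa(founders[f], rate_lo)
      aa[sprintf("hi_f%d_%d", f, k)] <- mutate_aa(founders[f], rate_hi)
    }
  }
  strains <- setNames(sub("_.*", "", names(aa)), names(aa))
  tree <- build_aa_tree(aa)
  cl <- extract_family_subtrees(tree, fraction)
  cluster_consensus_divergence(cl, aa, strains = strains)
}

# brute-force enumeration of maximal subtrees with height <= bound
brute_subtree_partition <- function(tree, fraction) {
  n <- ape::Ntip(tree)
  L <- tree_height(tree)
  if (L == 0) return(list(sort(tree$tip.label)))
  depth <- ape::node.depth.edgelength(tree)
  nn <- n + tree$Nnode
  height <- rep(0, nn)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    height[p] <- max(height[p], height[ch] + tree$edge.length[e])
  }
  qualifies <- height <= fraction * L + 1e-12
  # parent lookup
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  is_maximal <- function(v) {
    qualifies[v] && (is.na(parent[v]) || !qualifies[parent[v]])
  }
  roots <- which(vapply(seq_len(nn), is_maximal, TRUE))
  out <- lapply(roots, function(v) {
    tips <- if (v <= n) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
    sort(tips)
  })
  out[order(vapply(out, `[`, "", 1))]
}
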