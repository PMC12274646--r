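test_that("translation handles frames, partial codons and stops", {
  g <- data.frame(name = c("a", "b", "c"),
                  sequence = c("ATGGCC", "ATGTAAGCC", "ATGGCCA"))
  tr <- translate_and_filter(g)
  expect_equal(unname(tr$aa["a"]), "MA")
  expect_equal(unname(tr$aa["c"]), "MA")      # trailing base ignored
  expect_false("b" %in% names(tr$aa))         # in-frame stop discarded
  expect_equal(tr$discarded$reason, "stop codon")
  short <- translate_and_filter(data.frame(name = "x", sequence = "AT"))
  expect_equal(short$discarded$reason, "shorter than one codon")
})

test_that("per-gene mean identities match a brute-force oracle", {
  set.seed(91)
  aa <- setNames(vapply(1:5, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE),
          collapse = ""), ""), paste0("g", 1:5))
  res <- mean_pairwise_identity(aa)
  for (i in seq_along(aa)) {
    ids <- vapply(seq_along(aa)[-i], function(k)
      align(aa[[i]], aa[[k]], mode = "global", n_wildcard = FALSE,
            check_alphabet = FALSE)$percent_identity, 0)
    expect_equal(res$mean_identity[res$name == names(aa)[i]], mean(ids),
                 tolerance = 1e-9)
  }
  # identical sequences give 100; 1 difference in 100 residues gives 99
  same <- setNames(rep(strrep("M", 50), 3), c("x", "y", "z"))
  expect_true(all(mean_pairwise_identity(same)$mean_identity == 100))
  two <- c(p = strrep("A", 100), q = paste0(strrep("A", 99), "C"))
  expect_equal(mean_pairwise_identity(two)$mean_identity, c(99, 99))
  # singleton groups report NA
  single <- mean_pairwise_identity(c(two, r = strrep("C", 100)),
                                   grouping = c("u", "u", "v"))
  expect_true(is.na(single$mean_identity[single$group == "v"]))
})

test_that("identical sequences give a star tree of height zero", {
  aa <- setNames(rep(strrep("MKV", 20), 4), paste0("g", 1:4))
  tree <- build_aa_tree(aa)
  expect_equal(tree_height(tree), 0)
  expect_equal(extract_family_subtrees(tree), list(sort(names(aa))))
})

test_that("additive amino-acid distances are recovered exactly", {
  set.seed(92)
  ad <- random_additive_matrix(4)
  tree <- neighbor_joining(ad$d)
  expect_lt(max(abs(ape::cophenetic.phylo(tree)[rownames(ad$d), rownames(ad$d)]
                    - ad$d)), 1e-9)
})

test_that("subtree extraction partitions leaves and matches brute force", {
  set.seed(93)
  for (i in 1:20) {
    tree <- ape::rtree(sample(5:15, 1))
    for (fr in c(0.1, 0.3, 1)) {
      mine <- extract_family_subtrees(tree, fraction = fr)
      expect_setequal(unlist(mine), tree$tip.label)        # partition: no loss
      expect_equal(length(unlist(mine)), ape::Ntip(tree))  # no duplication
      oracle <- brute_subtree_partition(tree, fr)
      expect_equal(mine, oracle)
    }
  }
  expect_error(extract_family_subtrees(ape::rtree(4), fraction = 0), "fraction")
})

test_that("a long internal edge splits a caterpillar tree into two families", {
  tree <- ape::read.tree(text = "((a:0.01,b:0.01):0.5,(c:0.01,d:0.01):0.5);")
  cl <- extract_family_subtrees(tree, fraction = 0.1)
  expect_equal(cl, list(c("a", "b"), c("c", "d")))
})

test_that("consensus divergence reproduces the hand-computed example", {
  aa <- c(g1 = "AAAA", g2 = "AAAT", g3 = "AAAA")
  dt <- cluster_consensus_divergence(list(names(aa)), aa)
  expect_equal(dt$divergence[match(c("g1", "g2", "g3"), dt$gene)],
               c(0, 0.25, 0))
  # identical cluster -> all zero
  dt2 <- cluster_consensus_divergence(list(c("x", "y")),
                                      c(x = "MKVA", y = "MKVA"))
  expect_true(all(dt2$divergence == 0))
  expect_error(cluster_consensus_divergence(list("g1"), aa), "partition")
})

test_that("divergence is zero iff the gene equals the cluster consensus", {
  set.seed(94)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    cons <- paste(sample(alpha, 30, TRUE), collapse = "")
    aa <- c(a = cons, b = cons,
            c = paste0(substr(cons, 1, 29), setdiff(alpha, substr(cons, 30, 30))[1]))
    dt <- cluster_consensus_divergence(list(names(aa)), aa)
    expect_equal(dt$divergence[dt$gene == "a"], 0)
    expect_gt(dt$divergence[dt$gene == "c"], 0)
  }
})

test_that("higher mutation rates give higher mean divergence per strain", {
  set.seed(95)
  dt <- simulated_strain_divergence(rate_lo = 0.02, rate_hi = 0.1)
  means <- tapply(dt$divergence, dt$strain, mean)
  expect_gt(means[["hi"]], means[["lo"]])
})

test_that("a more diverged panel yields lower mean pairwise identity", {
  set.seed(96)
  founder <- rand_aa(60)
  heavy <- vapply(1:8, function(i) mutate_aa(founder, 0.25), "")
  light <- vapply(1:8, function(i) mutate_aa(founder, 0.05), "")
  names(heavy) <- paste0("h", 1:8); names(light) <- paste0("l", 1:8)
  mh <- mean(mean_pairwise_identity(heavy)$mean_identity)
  ml <- mean(mean_pairwise_identity(light)$mean_identity)
  expect_lt(mh, ml)
})
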