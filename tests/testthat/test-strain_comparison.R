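test_that("database representation flags exact matches as present", {
  set.seed(71)
  ref <- gset_from(c(rand_dna(300), rand_dna(300)), prefix = "IGKV")
  q <- germline_set(c("q1", "q2"),
                    c(ref$sequence[1],
                      paste0(substr(ref$sequence[2], 1, 150), "A",
                             substr(ref$sequence[2], 152, 300))),
                    segment = "V", locus = "IGK")
  rep <- db_representation(q, ref)
  expect_true(rep$present[rep$name == "q1"])
  expect_equal(rep$percent_identity[rep$name == "q1"], 100)
  r2 <- rep[rep$name == "q2", ]
  expect_false(r2$present)
  expect_equal(r2$percent_identity, 100 * 299 / 300, tolerance = 1e-6)
})

test_that("summary percentages reproduce printed roundings", {
  expect_equal(pct_label(311, 459, 1), "67.8%")
  expect_equal(pct_label(13, 22, 0), "59%")
  expect_equal(pct_label(74, 324, 0), "23%")
})

test_that("sharing sets count exact-sequence intersections", {
  set.seed(72)
  shared <- vapply(1:5, function(i) rand_dna(60), "")
  gA <- gset_from(shared, strain = "A")
  gB <- gset_from(shared, strain = "B")
  rep <- sharing_sets(list(A = gA, B = gB))
  expect_equal(rep$combinations$strains, "A+B")
  expect_equal(rep$combinations$count, 5L)
  # disjoint sets -> only singletons
  gC <- gset_from(vapply(1:4, function(i) rand_dna(60), ""), strain = "C")
  rep2 <- sharing_sets(list(A = gA, C = gC))
  expect_setequal(rep2$combinations$strains, c("A", "C"))
})

test_that("a planted sharing structure is reported exactly", {
  set.seed(73)
  all3 <- vapply(1:27, function(i) rand_dna(50), "")
  two <- vapply(1:14, function(i) rand_dna(50), "")
  pa <- vapply(1:6, function(i) rand_dna(50), "")
  pb <- vapply(1:4, function(i) rand_dna(50), "")
  pc <- vapply(1:9, function(i) rand_dna(50), "")
  g <- list(S1 = gset_from(c(all3, two, pa), strain = "S1"),
            S2 = gset_from(c(all3, two, pb), strain = "S2"),
            S3 = gset_from(c(all3, pc), strain = "S3"))
  rep <- sharing_sets(g)
  cmb <- setNames(rep$combinations$count, rep$combinations$strains)
  expect_equal(unname(cmb[["S1+S2+S3"]]), 27L)
  expect_equal(unname(cmb[["S1+S2"]]), 14L)
  expect_equal(unname(cmb[["S1"]]), 6L)
  expect_equal(unname(cmb[["S2"]]), 4L)
  expect_equal(unname(cmb[["S3"]]), 9L)
  # conservation: combination counts sum to the number of unique sequences
  expect_equal(sum(rep$combinations$count), nrow(rep$memberships))
  expect_equal(unname(rep$per_strain),
               c(27 + 14 + 6, 27 + 14 + 4, 27 + 9))
})

test_that("sharing counts agree with a brute-force intersection oracle", {
  set.seed(74)
  pool <- vapply(1:30, function(i) rand_dna(40), "")
  sets <- lapply(1:4, function(i) sample(pool, sample(10:20, 1)))
  names(sets) <- paste0("st", 1:4)
  g <- lapply(names(sets), function(s) gset_from(sets[[s]], strain = s))
  names(g) <- names(sets)
  rep <- sharing_sets(g)
  for (u in unique(unlist(sets))) {
    members <- names(sets)[vapply(sets, function(x) u %in% x, TRUE)]
    expect_equal(rep$memberships$strains[rep$memberships$sequence == u],
                 paste(sort(members), collapse = "+"))
  }
  expect_equal(sum(rep$combinations$count), length(unique(unlist(sets))))
})

test_that("pairwise set similarity follows the query and length rules", {
  set.seed(75)
  seqs <- vapply(1:3, function(i) rand_dna(285), "")
  gA <- gset_from(seqs, strain = "A")
  gB <- gset_from(seqs, strain = "B")
  sim <- pairwise_set_similarity(gA, gB)
  expect_equal(sim$mean_identity, 100)
  expect_equal(sim$n_excluded, 0L)
  # short allele: its only alignment spans < 275 nt -> excluded
  gShort <- germline_set(c("s1", "s2"), c(substr(seqs[1], 1, 200), seqs[2]),
                         segment = "V", locus = "IGK", strain = "S")
  sim2 <- pairwise_set_similarity(gShort, gA, min_alignment_length = 275)
  expect_equal(sim2$n_excluded, 1L)
  expect_equal(sim2$mean_identity, 100)
  # constructed identities {100, 99, 98} -> mean 99 (oracle-checkable)
  mk <- function(s, k) {
    if (k == 0) return(s)
    x <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) x[p * 7] <- setdiff(c("A","C","G","T"), x[p * 7])[1]
    paste(x, collapse = "")
  }
  q <- gset_from(c(seqs[1], mk(seqs[2], 3), mk(seqs[3], 6)), strain = "Q")
  ids <- c(100, 100 * (285 - 3) / 285, 100 * (285 - 6) / 285)
  sim3 <- pairwise_set_similarity(q, gA)
  expect_equal(sim3$mean_identity, mean(ids), tolerance = 1e-9)
})

test_that("similarity matrices are symmetric with diagonal 100", {
  set.seed(76)
  base <- vapply(1:4, function(i) rand_dna(285), "")
  mut <- function(s, r) {
    x <- strsplit(s, "")[[1]]
    hit <- which(runif(length(x)) < r)
    for (h in hit) x[h] <- sample(setdiff(c("A","C","G","T"), x[h]), 1)
    paste(x, collapse = "")
  }
  g <- list(S1 = gset_from(base, strain = "S1"),
            S2 = gset_from(vapply(base, mut, "", r = 0.01), strain = "S2"),
            S3 = gset_from(vapply(base, mut, "", r = 0.05), strain = "S3"))
  res <- similarity_matrix_and_clustering(g)
  expect_equal(res$matrix, t(res$matrix))
  expect_equal(unname(diag(res$matrix)), rep(100, 3))
  expect_true(all(res$matrix >= 0 & res$matrix <= 100))
  # input order must not matter
  res2 <- similarity_matrix_and_clustering(g[c(3, 1, 2)])
  expect_equal(res2$matrix[rownames(res$matrix), colnames(res$matrix)],
               res$matrix)
  expect_equal(res2$newick, res$newick)
})

test_that("strains with identical sets merge first in the dendrogram", {
  set.seed(77)
  base <- vapply(1:3, function(i) rand_dna(285), "")
  far <- vapply(1:3, function(i) rand_dna(285), "")
  g <- list(A = gset_from(base, strain = "A"),
            B = gset_from(base, strain = "B"),
            C = gset_from(far, strain = "C"))
  res <- similarity_matrix_and_clustering(g)
  first <- res$hclust$merge[1, ]
  expect_setequal(res$hclust$labels[-first], c("A", "B"))
})
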