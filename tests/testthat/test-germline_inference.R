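# helper: build a rearrangement table with given junctions and profiles
fake_rearr <- function(junctions, v_call = "IGKV1*01", ids = NULL,
                       allele = NULL) {
  n <- length(junctions)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  if (is.null(allele)) allele <- strrep("ACGT", 25)
  seqs <- paste0(allele, junctions)
  re <- rearrangements(ids, seqs, v_call, v_identity = 100,
                       v_start = 0L, v_end = nchar(allele),
                       j_region = junctions, dupcount = 1L)
  profs <- lapply(seq_len(n), function(i)
    list(bases = strsplit(allele, "")[[1]], delta = 0L, identity = 100,
         covered = nchar(allele)))
  names(profs) <- ids
  attr(re, "v_profiles") <- profs
  re
}

test_that("bimodal junction distances yield a threshold in the valley", {
  set.seed(51)
  flip <- function(s, k) {
    x <- strsplit(s, "")[[1]]
    for (p in sample(length(x), k)) x[p] <- sample(setdiff(c("A","C","G","T"), x[p]), 1)
    paste(x, collapse = "")
  }
  # clonally related pairs with nearest distance ~0.025, plus a diffuse
  # cloud around one anchor whose nearest distances sit near 0.2
  base <- rand_dna(40)
  pairs <- unlist(lapply(1:40, function(i) {
    anchor <- flip(base, 15)
    c(anchor, flip(anchor, 1))
  }))
  cloud <- vapply(1:30, function(i) flip(base, 4), "")
  re <- fake_rearr(c(pairs, cloud))
  expect_no_warning(thr <- estimate_clone_threshold(re))
  expect_gt(thr, 0.05)
  expect_lt(thr, 0.15)
})

test_that("degenerate distances fall back to 0.1 with a warning", {
  re <- fake_rearr(rep(strrep("AC", 20), 60))
  expect_warning(thr <- estimate_clone_threshold(re), "fallback|degenerate")
  expect_equal(thr, 0.1)
  expect_warning(thr2 <- estimate_clone_threshold(fake_rearr(c("AAAA", "AAAT"))),
                 "fewer than")
  expect_equal(thr2, 0.1)
})

test_that("clone grouping follows single linkage within V/junction partitions", {
  # identical junctions, same v_call -> one clone
  re <- fake_rearr(rep("ACGTACGTACGTACGTACGT", 2))
  cl <- group_clones(re, 0.1)
  expect_equal(nrow(cl$clones), 1L)
  # distance above threshold -> two clones
  re2 <- fake_rearr(c("AAAAAAAAAA", "AAAAATTTTT"))
  cl2 <- group_clones(re2, 0.2)
  expect_equal(nrow(cl2$clones), 2L)
  # chain A-B <= t, B-C <= t, A-C > t -> one clone (single linkage)
  re3 <- fake_rearr(c("AAAAAAAAAA", "AAAAAAAATT", "AAAAAATTTT"))
  cl3 <- group_clones(re3, 0.2)
  expect_equal(nrow(cl3$clones), 1L)
})

test_that("single-linkage clone grouping agrees with a brute-force oracle", {
  set.seed(52)
  for (rep_i in 1:5) {
    juncs <- vapply(1:30, function(i) rand_dna(20), "")
    re <- fake_rearr(juncs)
    thr <- 0.25
    cl <- group_clones(re, thr)
    dm <- airrgerm:::cpp_hamming_matrix(juncs) / 20
    oracle <- brute_single_linkage(dm, thr)
    mine <- as.integer(factor(cl$rearrangements$clone_id,
                              levels = unique(cl$rearrangements$clone_id)))
    # same partition up to relabelling
    expect_equal(length(unique(oracle)), length(unique(mine)))
    expect_true(all(tapply(oracle, mine, function(x) length(unique(x))) == 1))
  }
})

test_that("noiseless clones from one allele give that allele with support 1", {
  set.seed(53)
  allele <- rand_dna(285)
  juncs <- vapply(1:40, function(i) rand_dna(12), "")
  re <- fake_rearr(juncs, allele = allele)
  cl <- group_clones(re, 0.1)
  ref <- germline_set("IGKV1*01", allele, segment = "V", locus = "IGK")
  inf <- infer_v_germline(cl, ref, min_clones = 2L)
  expect_equal(nrow(inf), 1L)
  expect_equal(inf$sequence, allele)
  expect_equal(inf$support_fraction, 1)
  expect_equal(inf$status, "inferred-known")
  expect_equal(inf$name, "IGKV1*01")
})

test_that("clusters below the support rules are discarded", {
  set.seed(54)
  a1 <- rand_dna(285)
  a2 <- .mutate <- paste0(substr(a1, 1, 100),
                          chartr("ACGT", "CAGT", substr(a1, 101, 110)),
                          substr(a1, 111, 285))
  juncs <- vapply(1:100, function(i) rand_dna(12), "")
  re <- fake_rearr(juncs, allele = a1)
  # plant 2 clones of a second allele (2% < min_clones = 5)
  profs <- attr(re, "v_profiles")
  for (i in 99:100) {
    re$sequence[i] <- paste0(a2, re$j_region[i])
    profs[[i]]$bases <- strsplit(a2, "")[[1]]
  }
  attr(re, "v_profiles") <- profs
  cl <- group_clones(re, 0.1)
  ref <- germline_set("IGKV1*01", a1, segment = "V", locus = "IGK")
  inf <- infer_v_germline(cl, ref, min_clones = 5L)
  expect_equal(inf$sequence, a1)   # the rare variant was dropped
})

test_that("two co-alleles differing at one position are both recovered", {
  set.seed(55)
  a1 <- rand_dna(285)
  a2 <- paste0(substr(a1, 1, 139),
               setdiff(c("A", "C", "G", "T"), substr(a1, 140, 140))[1],
               substr(a1, 141, 285))
  n <- 400
  alleles <- rep(c(a1, a2), n / 2)
  juncs <- vapply(seq_len(n), function(i) rand_dna(12), "")
  ids <- sprintf("r%04d", seq_len(n))
  seqs <- paste0(alleles, juncs)
  # SHM 1% per base on the V portion
  muts <- integer(n)
  for (i in seq_len(n)) {
    x <- strsplit(substr(seqs[i], 1, 285), "")[[1]]
    hit <- which(runif(285) < 0.01)
    for (h in hit) x[h] <- sample(setdiff(c("A","C","G","T"), x[h]), 1)
    seqs[i] <- paste0(paste(x, collapse = ""), juncs[i])
    muts[i] <- length(hit)
  }
  re <- rearrangements(ids, seqs, "IGKV1*01", v_identity = 100 * (285 - muts) / 285,
                       v_start = 0L, v_end = 285L, j_region = juncs)
  profs <- lapply(seq_len(n), function(i)
    list(bases = strsplit(substr(seqs[i], 1, 285), "")[[1]], delta = 4L,
         identity = 100 * (285 - muts[i]) / 285, covered = 285L))
  names(profs) <- ids
  attr(re, "v_profiles") <- profs
  cl <- group_clones(re, 0.1)
  ref <- germline_set("IGKV1*01", a1, segment = "V", locus = "IGK")
  inf <- infer_v_germline(cl, ref)
  expect_setequal(inf$sequence, c(a1, a2))
})

test_that("inference output is invariant to read order", {
  cfg <- tiny_config(seed = 56, n_v = 4, read_depth = 1500)
  pan <- simulate_germline_panel(cfg)
  rep <- simulate_repertoire(pan$strains$s1, cfg)
  res1 <- infer_germline_pipeline(rep$r1, rep$r2, pan$reference, polish = FALSE)
  set.seed(99)
  perm <- sample(nrow(rep$r1))
  res2 <- infer_germline_pipeline(rep$r1[perm, ], rep$r2[perm, ],
                                  pan$reference, polish = FALSE)
  expect_equal(res1$inferred$sequence, res2$inferred$sequence)
  expect_equal(res1$inferred$n_clones, res2$inferred$n_clones)
})

test_that("support fractions never sum above 1", {
  cfg <- tiny_config(seed = 57, n_v = 5, read_depth = 1500)
  pan <- simulate_germline_panel(cfg)
  rep <- simulate_repertoire(pan$strains$s1, cfg)
  res <- infer_germline_pipeline(rep$r1, rep$r2, pan$reference, polish = FALSE)
  expect_lte(sum(res$inferred$support_fraction), 1 + 1e-12)
})

test_that("genotype validation retains supported alleles and drops ties", {
  set.seed(58)
  a1 <- rand_dna(150); a2 <- rand_dna(150)
  inferred <- data.frame(
    name = c("X1", "X2"), sequence = c(a1, a2), n_clones = c(10L, 10L),
    support_fraction = c(0.5, 0.5), nearest_reference = c("X1", "X2"),
    nearest_identity = c(100, 100),
    status = "inferred-known", stringsAsFactors = FALSE)
  class(inferred) <- c("inferred_alleles", "data.frame")
  reads <- seq_records(sprintf("r%02d", 1:10), rep(a1, 10))
  val <- validate_genotype(inferred, reads, min_exact = 3L)
  expect_equal(val$validated$name, "X1")
  expect_equal(val$removed, "X2")
  # all supporters tie between two identical alleles -> both removed
  inferred2 <- inferred
  inferred2$sequence <- c(a1, a1)
  val2 <- validate_genotype(inferred2, reads, min_exact = 3L)
  expect_equal(nrow(val2$validated), 0L)
})
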