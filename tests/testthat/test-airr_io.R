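test_that("FASTA load preserves ids and sequences, dupcount starts at 1", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTACGT", ">r2", "GGGTTTAA"), tf)
  rec <- read_sequences(tf)
  expect_equal(rec$id, c("r1", "r2"))
  expect_equal(rec$sequence, c("ACGTACGT", "GGGTTTAA"))
  expect_equal(rec$dupcount, c(1L, 1L))
})

test_that("malformed records and contract violations fail with located errors", {
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), tf)   # quality shorter than sequence
  expect_error(read_sequences(tf, format = "fastq"), "line 4")
  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT"), tf2)
  expect_error(read_sequences(tf2, format = "fasta"), "line 1")
  tf3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGG"), tf3)
  expect_error(read_sequences(tf3), "duplicate")
  expect_error(seq_records("x", "ACGU"), "RNA|DNA")
  expect_error(seq_records("x", "ACGR"), "disallowed")
})

test_that("sequence round-trip through FASTA and FASTQ is exact", {
  set.seed(11)
  n <- 100
  rec <- seq_records(sprintf("read%03d", 1:n),
                     vapply(1:n, function(i) rand_dna(sample(30:80, 1)), ""))
  rec$quality <- vapply(nchar(rec$sequence), function(k)
    paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]], k, TRUE),
          collapse = ""), "")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(rec, fa, format = "fasta")
  back <- read_sequences(fa)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_sequences(rec, fq, format = "fastq")
  back <- read_sequences(fq, format = "fastq")
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$quality, rec$quality)
})

test_that("AIRR TSV round-trip is field-identical and converts coordinates", {
  set.seed(12)
  n <- 50
  seqs <- vapply(1:n, function(i) rand_dna(120), "")
  re <- rearrangements(
    sequence_id = sprintf("s%02d", 1:n), sequence = seqs,
    v_call = sample(c("IGKV1*01", "IGKV2*01"), n, TRUE),
    j_call = sample(c("IGKJ1*01", ""), n, TRUE),
    v_identity = round(runif(n, 90, 100), 3),
    v_start = 0L, v_end = 80L,
    j_start = NA_integer_, j_end = NA_integer_,
    j_region = substr(seqs, 81, 120),
    clone_id = sprintf("c%02d", 1:n), dupcount = sample(1:9, n, TRUE))
  has_j <- re$j_call != ""
  re$j_start[has_j] <- 85L
  re$j_end[has_j] <- 120L
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_airr(re, tf)
  raw <- utils::read.delim(tf)
  expect_equal(raw$v_sequence_start[1], 1L)      # 0-based -> 1-based inclusive
  back <- read_airr(tf)
  expect_equal(back, re, ignore_attr = TRUE)
})

test_that("AIRR reader handles empty tables and reports missing columns", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence_id\tsequence\tv_call\tj_call", tf)
  expect_equal(nrow(read_airr(tf)), 0L)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tsequence\tv_call", "a\tACGT\tV1"), tf2)
  expect_error(read_airr(tf2), "j_call")
})

test_that("rearrangement invariants are enforced", {
  expect_error(rearrangements("a", "ACGTACGT", "V1", v_start = 5L, v_end = 3L),
               "V coordinates")
  expect_error(rearrangements("a", "ACGTACGT", "V1", v_start = 0L, v_end = 6L,
                              j_start = 2L, j_end = 8L, j_call = "J1"),
               "precede")
  expect_error(rearrangements("a", "ACGTACGT", "V1", v_start = 0L, v_end = 4L,
                              v_identity = 105), "identity")
})

test_that("germline sets collapse duplicate sequences and order by name", {
  g <- germline_set(c("b", "a", "c"), c("ACGT", "GGCC", "ACGT"),
                    segment = "V", locus = "IGK")
  expect_equal(nrow(g), 2L)
  expect_equal(attr(g, "n_collapsed"), 1L)
  expect_equal(g$name, c("a", "b"))
  expect_error(germline_set("x", "ACNT"), "disallowed")
  expect_error(germline_set(c("x", "x"), c("AAAA", "CCCC")), "duplicate")
})

test_that("genotype matrices reject heterozygous codes and bad masks", {
  m <- matrix(c("A", "C", "G", "T"), 2, 2, dimnames = list(c("s1", "s2"), NULL))
  expect_s3_class(genotype_matrix(m), "genotype_matrix")
  m2 <- m; m2[1, 1] <- "R"
  expect_error(genotype_matrix(m2), "homozygous")
  expect_error(genotype_matrix(m, mask = TRUE), "mask length")
})

test_that("Newick round-trip preserves topology, labels and lengths", {
  set.seed(13)
  tree <- ape::rtree(12)
  tree$edge.length <- round(tree$edge.length, 6)
  tf <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, tf)
  back <- ape::read.tree(tf)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_equal(ape::cophenetic.phylo(back)[tree$tip.label, tree$tip.label],
               ape::cophenetic.phylo(tree), tolerance = 1e-6)
})
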