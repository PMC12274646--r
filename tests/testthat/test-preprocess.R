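IGLV1_PRIMER <- "AGCTCTTCAGAGGAAGGTGG"

test_that("printed 5'RACE primer is located, masked, and G-run trimmed", {
  pset <- primer_set(c(IGLV1 = IGLV1_PRIMER))
  read <- seq_records("r1", paste0(IGLV1_PRIMER, "GGGG", "ATTCCGATGCA"))
  out <- mask_primers(read, pset)
  expect_true(out$primer_matched)
  expect_equal(out$primer, "IGLV1")
  expect_equal(out$sequence, paste0(strrep("N", 20), "ATTCCGATGCA"))
})

test_that("primer matching tolerates mismatches up to the limit", {
  pset <- primer_set(c(P = "ACGTACGTACGTACGT"), max_mismatches = 2L)
  body <- "TTTTCCCCGGGGAAAA"
  one_mm <- sub("^A", "C", "ACGTACGTACGTACGT")
  out <- mask_primers(seq_records("r", paste0(one_mm, body)), pset)
  expect_true(out$primer_matched)
  # brute-force oracle: best offset/mismatch over the search window
  scan <- airrgerm:::cpp_scan_primer(paste0(one_mm, body), "ACGTACGTACGTACGT", 2L, 30L)
  expect_equal(scan$mismatches, 1L)
  expect_equal(scan$offset, 0L)
  three_mm <- paste0("CCCC", substr("ACGTACGTACGTACGT", 5, 16))
  out2 <- mask_primers(seq_records("r", paste0(three_mm, body)), pset)
  expect_false(out2$primer_matched)
  expect_equal(out2$sequence, paste0(three_mm, body))  # unchanged
})

test_that("mask_primers is idempotent", {
  pset <- primer_set(c(IGLV1 = IGLV1_PRIMER))
  read <- seq_records("r1", paste0(IGLV1_PRIMER, "GGG", "ATTCCGATG"))
  once <- mask_primers(read, pset)
  twice <- mask_primers(once[, names(read)], pset)
  expect_false(twice$primer_matched)   # primer is gone after masking
  expect_equal(twice$sequence, once$sequence)
})

test_that("pair merging arithmetic and failure reporting", {
  set.seed(31)
  core <- rand_dna(550)
  r1 <- list(sequence = substr(core, 1, 300), quality = strrep("I", 300))
  r2 <- list(sequence = revcomp(substr(core, 251, 550)),
             quality = strrep("I", 300))
  m <- merge_pair(r1, r2, min_overlap = 20)
  expect_true(m$success)
  expect_equal(nchar(m$sequence), 550L)   # 300 + 300 - 50
  expect_equal(m$overlap, 50L)
  expect_equal(m$sequence, core)
  # no qualifying overlap
  bad <- merge_pair(list(sequence = rand_dna(100), quality = NA),
                    list(sequence = rand_dna(100), quality = NA),
                    min_overlap = 30)
  expect_false(isTRUE(bad$success))
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  set.seed(35)
  core <- rand_dna(120)
  s1 <- substr(core, 1, 80)
  s2 <- substr(core, 41, 120)
  # plant a disagreement inside the overlap (position 59 of the molecule)
  true59 <- substr(core, 59, 59)
  wrong <- setdiff(c("A", "C", "G", "T"), true59)[1]
  s1err <- paste0(substr(s1, 1, 58), wrong, substr(s1, 60, 80))
  q1 <- paste0(strrep("I", 58), "#", strrep("I", 21))   # low quality at error
  m <- merge_pair(list(sequence = s1err, quality = q1),
                  list(sequence = revcomp(s2), quality = strrep("I", 80)),
                  min_overlap = 20)
  expect_true(m$success)
  expect_equal(m$sequence, core)        # r2's high-quality base won
  # with equal qualities the tie goes to r1
  m2 <- merge_pair(list(sequence = s1err, quality = strrep("I", 80)),
                   list(sequence = revcomp(s2), quality = strrep("I", 80)),
                   min_overlap = 20)
  expect_equal(substr(m2$sequence, 59, 59), wrong)
})

test_that("duplicate collapsing conserves counts and filters singletons", {
  rec <- seq_records(c("a", "b", "c", "d"),
                     c("ACGTACGT", "ACGTACGT", "ACGTACGT", "TTTTAAAA"))
  out <- collapse_duplicates(rec)
  expect_equal(out$n_input, 4L)
  expect_equal(out$n_unique, 2L)
  expect_equal(out$records$dupcount, 3L)     # only the triplet survives
  expect_equal(out$records$id, "a")          # smallest member id
  all_distinct <- seq_records(letters[1:5],
                              vapply(1:5, function(i) rand_dna(20), ""))
  expect_equal(nrow(collapse_duplicates(all_distinct)$records), 0L)
})

test_that("dupcount totals are conserved on random inputs", {
  set.seed(32)
  for (rep in 1:3) {
    pool <- vapply(1:50, function(i) rand_dna(30), "")
    seqs <- sample(pool, 1000, replace = TRUE)
    rec <- seq_records(sprintf("r%04d", 1:1000), seqs)
    out <- collapse_duplicates(rec, min_dupcount = 1L)
    expect_equal(sum(out$records$dupcount), 1000L)
    expect_equal(nrow(out$records), length(unique(seqs)))
  }
})

test_that("noiseless simulated pairs merge back to the exact molecule", {
  cfg <- tiny_config(seed = 33, n_v = 3, read_depth = 100)
  pan <- simulate_germline_panel(cfg)
  rep <- simulate_repertoire(pan$strains$s1, cfg, n_molecules = 30)
  mg <- merge_pairs(rep$r1, rep$r2)
  expect_equal(mg$n_failed, 0L)
  # merged length equals the molecule length (primer + G run + leader + core)
  expect_true(all(nchar(mg$merged$sequence) > 300))
})

test_that("empty primer sets are rejected", {
  expect_error(primer_set(character()), "at least one")
  expect_error(primer_set(c("ACGT")), "names")
})
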