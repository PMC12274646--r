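# Simulation of multi-strain germline panels, 5'RACE repertoire reads and
# SNP genotype matrices with known ground truth. The generator emulates the
# structure of mouse light-chain 5'RACE MiSeq libraries: a 5' primer,
# a template-switch G-run, a (possibly 5'-truncated) V segment, a trimmed
# V-J junction with a short random N-region, a constant-region stub, PCR
# duplication and per-base sequencing error.

#' Built-in 5'RACE primer set
#'
#' The four 5' primer sequences determined for mouse light-chain 5'RACE
#' BCR libraries by aligning the first 30 bp of forward reads.
#'
#' @format named character vector of 5'->3' primer sequences.
#' @export
DEFAULT_PRIMERS <- c(IGLV1     = "AGCTCTTCAGAGGAAGGTGG",
                     IGLC_var1 = "AGCTCTTCAGGGGAAGGTGG",
                     IGLC2     = "AGCTCCTCAGAGGAAGGTGG",
                     IGLC3     = "AGCTCCTCAGGGGAAGGTGG")

# fixed constant-region stubs giving J extraction a right boundary
CONSTANT_STUB <- c(IGK = "GGCTGATGCTGCACCAACTGTATCCATCTT",
                   IGL = "GGTCAGCCCAAGTCTTCGCCATCAGTCACC",
                   IGH = "GAGTCAGCCCGAACCTCTGTCTTCCCACTG")

.rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# substitute each base independently with probability `rate`; when
# min_subs > 0, redraw until at least that many substitutions were made
.mutate_seq <- function(seq, rate, min_subs = 0L) {
  x <- strsplit(seq, "")[[1]]
  repeat {
    hit <- which(runif(length(x)) < rate)
    if (length(hit) >= min_subs) break
    if (rate <= 0) { hit <- sample(length(x), min_subs); break }
  }
  for (i in hit) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
  paste(x, collapse = "")
}

#' Simulation configuration
#'
#' Bundles every tunable of the repertoire simulator. Defaults reflect a
#' mouse light-chain 5'RACE library: 285-nt V and 38-nt J alleles, 2x300
#' read geometry with overlapping pairs, somatic hypermutation at 2% per
#' base, sequencing error at 0.3% per base, and a mean of 3 PCR duplicates
#' per molecule.
#'
#' @param seed integer seed driving all randomness.
#' @param haplotype_groups named list of character vectors partitioning the
#'   strains into haplotype groups.
#' @param shared_fraction fraction of group alleles shared exactly by every
#'   strain of a group (remaining alleles are strain-private).
#' @param n_v,n_j number of V and J founder alleles per locus.
#' @param v_length,j_length allele lengths in nt.
#' @param group_divergence,strain_divergence per-base substitution rates used
#'   to derive group alleles from founders and strain-private alleles from
#'   group alleles.
#' @param known_fraction probability that a group allele equals its founder
#'   exactly (emulating alleles already documented in the reference database).
#' @param shm_rate per-base somatic hypermutation probability per molecule.
#' @param read_depth read pairs per strain.
#' @param dup_mean mean sequencing duplicates per molecule (k = 1 + Poisson).
#' @param error_rate per-base sequencing error probability per read copy.
#' @param primer_set named 5' primer sequences.
#' @param g_run_length template-switch G-run length.
#' @param read_length read length in nt (2x300 MiSeq geometry by default).
#' @param trunc_prob,trunc_max probability and maximal extent (nt) of V 5'
#'   truncation of a molecule.
#' @param novel_j_spec optional list(strain=, j_name=, usage=) planting a
#'   single-SNP novel J allele used by the given fraction of molecules.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       haplotype_groups = list(A = c("strain1", "strain2")),
                       shared_fraction = 0.8,
                       n_v = 40L, n_j = 4L,
                       v_length = 285L, j_length = 38L,
                       group_divergence = 0.015, strain_divergence = 0.008,
                       known_fraction = 0.3,
                       shm_rate = 0.02,
                       read_depth = 20000L, dup_mean = 3,
                       error_rate = 0.003,
                       primer_set = DEFAULT_PRIMERS,
                       g_run_length = 3L,
                       read_length = 300L,
                       trunc_prob = 0.1, trunc_max = 15L,
                       novel_j_spec = NULL) {
  probs <- c(shared_fraction = shared_fraction, known_fraction = known_fraction,
             shm_rate = shm_rate, error_rate = error_rate,
             trunc_prob = trunc_prob,
             group_divergence = group_divergence,
             strain_divergence = strain_divergence)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) stop("probabilities must lie in [0, 1]: ",
                        paste(bad, collapse = ", "))
  if (!is.null(novel_j_spec)) {
    stopifnot(is.list(novel_j_spec),
              all(c("strain", "j_name", "usage") %in% names(novel_j_spec)))
    if (novel_j_spec$usage < 0 || novel_j_spec$usage > 1)
      stop("novel J usage must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), haplotype_groups = haplotype_groups,
                 shared_fraction = shared_fraction, n_v = as.integer(n_v),
                 n_j = as.integer(n_j), v_length = as.integer(v_length),
                 j_length = as.integer(j_length),
                 group_divergence = group_divergence,
                 strain_divergence = strain_divergence,
                 known_fraction = known_fraction, shm_rate = shm_rate,
                 read_depth = as.integer(read_depth), dup_mean = dup_mean,
                 error_rate = error_rate, primer_set = primer_set,
                 g_run_length = as.integer(g_run_length),
                 read_length = as.integer(read_length),
                 trunc_prob = trunc_prob, trunc_max = as.integer(trunc_max),
                 novel_j_spec = novel_j_spec),
            class = "sim_config")
}

#' Simulate a multi-strain germline panel
#'
#' Generates a founder ("reference database") allele set, per-group variants
#' of each founder, and per-strain germline sets in which strains of the
#' same haplotype group share `shared_fraction` of their V alleles exactly
#' while the remainder are strain-private variants. All sequences derived
#' from the same founder are kept distinct by construction, so sharing
#' counts are exact. J alleles are shared across all strains (plus an
#' optional planted novel J).
#'
#' @param config a [sim_config()].
#' @param locus locus label for the panel.
#' @return a list with elements `strains` (named list of [germline_set()]),
#'   `reference` (founder `germline_set`), `truth` (data.frame of every
#'   planted allele with its founder and sharing structure) and `config`.
#' @export
simulate_germline_panel <- function(config, locus = "IGK") {
  set.seed(config$seed)
  strains <- unlist(config$haplotype_groups, use.names = FALSE)
  if (anyDuplicated(strains)) stop("a strain may appear in only one haplotype group")

  fam <- (seq_len(config$n_v) - 1L) %/% 5L + 1L
  v_names <- sprintf("%sV%d-%d*01", locus, fam, seq_len(config$n_v))
  founders_v <- vapply(seq_len(config$n_v), function(i) .rand_dna(config$v_length), "")
  j_names <- sprintf("%sJ%d*01", locus, seq_len(config$n_j))
  founders_j <- vapply(seq_len(config$n_j), function(i) .rand_dna(config$j_length), "")

  # registry of sequences per founder so derived alleles stay distinct
  seen <- lapply(founders_v, function(s) s)
  derive <- function(i, rate) {
    repeat {
      cand <- .mutate_seq(founders_v[i], rate, min_subs = 1L)
      if (!cand %in% seen[[i]]) { seen[[i]] <<- c(seen[[i]], cand); return(cand) }
    }
  }

  n_shared <- round(config$shared_fraction * config$n_v)
  truth <- list()
  sets <- list()
  for (g in names(config$haplotype_groups)) {
    group_alleles <- character(config$n_v)
    for (i in seq_len(config$n_v)) {
      group_alleles[i] <- if (runif(1) < config$known_fraction) founders_v[i]
      else derive(i, config$group_divergence)
    }
    shared_idx <- seq_len(n_shared)
    for (s in config$haplotype_groups[[g]]) {
      seqs <- character(config$n_v)
      for (i in seq_len(config$n_v)) {
        seqs[i] <- if (i %in% shared_idx) group_alleles[i]
        else derive(i, max(config$strain_divergence, 1e-9))
      }
      j_seqs <- founders_j
      j_nm <- j_names
      j_status <- rep("inferred-known", config$n_j)
      novel <- config$novel_j_spec
      if (!is.null(novel) && identical(novel$strain, s)) {
        base <- match(novel$j_name, j_names)
        if (is.na(base)) stop("novel_j_spec names unknown J allele: ", novel$j_name)
        # the planted SNP avoids the first five J bases: a polymorphism
        # there is partly or wholly confounded with junctional nucleotides
        # (5' trimming discounts its read evidence below the detection
        # rule), and reported novel J alleles carry interior SNPs
        jf <- strsplit(founders_j[base], "")[[1]]
        pos <- sample(seq.int(6L, length(jf)), 1L)
        jf[pos] <- sample(setdiff(DNA_BASES, jf[pos]), 1L)
        j_seqs <- c(j_seqs, paste(jf, collapse = ""))
        j_nm <- c(j_nm, paste0(novel$j_name, "_S1"))
        j_status <- c(j_status, "inferred-novel")
      }
      sets[[s]] <- germline_set(
        name = c(v_names, j_nm), sequence = c(seqs, j_seqs),
        segment = rep(c("V", "J"), c(config$n_v, length(j_nm))),
        locus = locus, strain = s,
        status = c(ifelse(seqs == founders_v, "inferred-known", "inferred-novel"),
                   j_status))
      truth[[s]] <- data.frame(
        strain = s, group = g, name = c(v_names, j_nm),
        segment = rep(c("V", "J"), c(config$n_v, length(j_nm))),
        founder = c(v_names, j_nm[seq_len(config$n_j)],
                    if (length(j_nm) > config$n_j) novel$j_name),
        sequence = c(seqs, j_seqs),
        shared = c(seq_len(config$n_v) %in% shared_idx,
                   rep(TRUE, config$n_j),
                   if (length(j_nm) > config$n_j) FALSE),
        stringsAsFactors = FALSE)
    }
  }
  reference <- germline_set(
    name = c(v_names, j_names), sequence = c(founders_v, founders_j),
    segment = rep(c("V", "J"), c(config$n_v, config$n_j)),
    locus = locus, status = "reference")
  list(strains = sets, reference = reference,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       config = config)
}

#' Simulate a 5'RACE repertoire for one strain
#'
#' Each molecule is primer + G-run + 5'UTR/leader + (possibly 5'-truncated)
#' V + junction
#' (0-3 nt trimmed from the V 3' end and the J 5' end, 0-4 random inserted
#' nt) + J + constant stub, with SHM applied per base at `shm_rate`. Each
#' molecule is emitted `1 + Poisson(dup_mean - 1)` times with independent
#' sequencing errors at `error_rate`. Read pairs follow 2x300 geometry and
#' always overlap.
#'
#' @param gset a [germline_set()] with at least one V and one J allele.
#' @param config a [sim_config()].
#' @param seed RNG seed for this repertoire (defaults to `config$seed + 1`;
#'   keep below 2^31).
#' @param n_molecules number of distinct molecules; defaults to
#'   `read_depth / dup_mean` so that the total read count matches
#'   `read_depth` in expectation.
#' @return list with `r1`, `r2` (sequence-record tables, R2 in sequencing
#'   orientation) and `truth` (one row per read pair).
#' @export
simulate_repertoire <- function(gset, config, seed = config$seed + 1L,
                                n_molecules = NULL) {
  v <- gset[gset$segment == "V", , drop = FALSE]
  j <- gset[gset$segment == "J", , drop = FALSE]
  if (nrow(v) < 1L || nrow(j) < 1L)
    stop("germline set must contain at least one V and one J allele")
  if (is.null(n_molecules))
    n_molecules <- max(1L, round(config$read_depth / config$dup_mean))
  if (config$read_depth == 0L) {
    warning("read_depth is 0; returning empty repertoire")
    empty <- seq_records(character(), character())
    return(list(r1 = empty, r2 = empty,
                truth = data.frame(read_id = character())))
  }
  set.seed(seed)
  locus <- attr(gset, "locus")
  stub <- CONSTANT_STUB[[locus]]
  novel <- config$novel_j_spec
  novel_name <- if (!is.null(novel)) paste0(novel$j_name, "_S1") else NA_character_
  use_novel_model <- !is.null(novel) && novel_name %in% j$name
  plain_j <- if (use_novel_model) which(j$name != novel_name) else seq_len(nrow(j))

  rl <- config$read_length
  nm <- n_molecules
  vi <- sample.int(nrow(v), nm, replace = TRUE)
  ji <- if (use_novel_model) {
    ifelse(runif(nm) < novel$usage, which(j$name == novel_name),
           plain_j[sample.int(length(plain_j), nm, replace = TRUE)])
  } else plain_j[sample.int(length(plain_j), nm, replace = TRUE)]
  v_trim <- sample(0:3, nm, replace = TRUE)
  j_trim <- sample(0:3, nm, replace = TRUE)
  ins_len <- sample(0:4, nm, replace = TRUE)
  trunc <- ifelse(runif(nm) < config$trunc_prob,
                  sample.int(config$trunc_max, nm, replace = TRUE), 0L)
  primer_i <- sample.int(length(config$primer_set), nm, replace = TRUE)
  leader_len <- sample(14:29, nm, replace = TRUE)
  grun <- strrep("G", config$g_run_length)

  mols <- character(nm); n_shm <- integer(nm)
  for (m in seq_len(nm)) {
    vseq <- v$sequence[vi[m]]
    vpart <- substr(vseq, trunc[m] + 1L, nchar(vseq) - v_trim[m])
    jpart <- substr(j$sequence[ji[m]], j_trim[m] + 1L, nchar(j$sequence[ji[m]]))
    core <- paste0(vpart, if (ins_len[m]) .rand_dna(ins_len[m]) else "",
                   jpart, stub)
    if (config$shm_rate > 0) {
      hit <- which(runif(nchar(core)) < config$shm_rate)
      if (length(hit)) {
        x <- strsplit(core, "")[[1]]
        for (h in hit) x[h] <- sample(setdiff(DNA_BASES, x[h]), 1L)
        core <- paste(x, collapse = "")
      }
      n_shm[m] <- length(hit)
    }
    # 5'UTR/leader between the template-switch G-run and the V start (it
    # never starts with G, so G-run trimming cannot eat into it or the V).
    # A 5'-truncated molecule has no leader: reverse transcription stalled
    # inside the V, and the template switch happened at the stall point.
    leader <- if (trunc[m] > 0L) ""
    else paste0(sample(c("A", "C", "T"), 1L), .rand_dna(leader_len[m] - 1L))
    mols[m] <- paste0(config$primer_set[[primer_i[m]]], grun, leader, core)
  }
  lm <- nchar(mols)
  r1m <- substr(mols, 1L, pmin(rl, lm))
  r2m <- revcomp(substr(mols, pmax(1L, lm - rl + 1L), lm))
  k <- 1L + rpois(nm, max(config$dup_mean - 1, 0))
  mol_of <- rep(seq_len(nm), k)
  dup_no <- sequence(k)
  ids <- sprintf("mol%07d_d%d", mol_of, dup_no)
  e1 <- vapply(mol_of, function(m) .seq_errors(r1m[m], config$error_rate), "")
  e2 <- vapply(mol_of, function(m) .seq_errors(r2m[m], config$error_rate), "")
  truth <- data.frame(
    read_id = ids, molecule_id = sprintf("mol%07d", mol_of),
    strain = attr(gset, "strain"),
    v_allele = v$name[vi[mol_of]], j_allele = j$name[ji[mol_of]],
    v_trunc = trunc[mol_of], v_trim = v_trim[mol_of],
    j_trim = j_trim[mol_of], insert_len = ins_len[mol_of],
    n_shm = n_shm[mol_of],
    novel_j = use_novel_model & j$name[ji[mol_of]] == novel_name,
    stringsAsFactors = FALSE)
  list(r1 = seq_records(ids, e1, quality = strrep("I", nchar(e1))),
       r2 = seq_records(ids, e2, quality = strrep("I", nchar(e2))),
       truth = truth)
}

.seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  hit <- which(runif(nchar(seq)) < rate)
  for (h in hit) {
    base <- substr(seq, h, h)
    substr(seq, h, h) <- sample(setdiff(DNA_BASES, base), 1L)
  }
  seq
}

#' Reverse complement
#' @param x character vector of DNA sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a strain-by-position SNP genotype matrix
#'
#' Each haplotype group receives an independent random ancestor genotype;
#' strains deviate from their group ancestor at `within_rate` per position,
#' so within-group distances are much smaller than between-group distances
#' by construction. Cells are set to `N` independently at `missing_rate`.
#'
#' @param groups named list of character vectors of strain names (>= 2
#'   groups).
#' @param n_positions number of SNP positions (>= 1).
#' @param missing_rate per-cell probability of a missing (`N`) genotype.
#' @param seed RNG seed.
#' @param within_rate per-position substitution rate within a group.
#' @return a [genotype_matrix()].
#' @export
simulate_snp_matrix <- function(groups, n_positions, missing_rate = 0.05,
                                seed = 1L, within_rate = 0.02) {
  if (length(groups) < 2L) stop("at least two haplotype groups are required")
  if (n_positions < 1L) stop("n_positions must be >= 1")
  set.seed(seed)
  strains <- unlist(groups, use.names = FALSE)
  m <- matrix("", nrow = length(strains), ncol = n_positions,
              dimnames = list(strains, sprintf("pos%04d", seq_len(n_positions))))
  for (g in groups) {
    anc <- sample(DNA_BASES, n_positions, replace = TRUE)
    for (s in g) {
      row <- anc
      hit <- which(runif(n_positions) < within_rate)
      for (h in hit) row[h] <- sample(setdiff(DNA_BASES, row[h]), 1L)
      m[s, ] <- row
    }
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(length(m)) < missing_rate, nrow = nrow(m))
    m[miss] <- "N"
  }
  genotype_matrix(m)
}
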