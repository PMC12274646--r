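# Domain containers and readers/writers for the standard formats the
# pipeline touches: FASTA/FASTQ, AIRR Rearrangement TSV, Newick (via ape),
# plain TSV for matrices. Internal coordinates are 0-based half-open; the
# AIRR TSV dialect on disk is 1-based inclusive.

DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pat, x))
  if (length(bad)) {
    chars <- unique(strsplit(gsub(if (allow_n) "[ACGTN]" else "[ACGT]", "",
                                  paste(x[bad], collapse = "")), "")[[1]])
    stop(what, " ", bad[1], " contains disallowed characters (",
         paste(chars, collapse = ", "),
         "); only A/C/G/T", if (allow_n) "/N", " are accepted", call. = FALSE)
  }
  invisible(x)
}

.norm_seq <- function(x) {
  x <- toupper(x)
  if (any(grepl("U", x, fixed = TRUE)))
    stop("RNA alphabet (U) is not accepted; sequences must be DNA", call. = FALSE)
  x
}

#' Construct a collection of sequence records
#'
#' A sequence-record table is a plain `data.frame` with columns `id`,
#' `sequence` (A/C/G/T, N permitted for masked bases), `quality` (Sanger
#' encoded, `NA` when absent) and `dupcount` (integer >= 1).
#'
#' @param id character vector of unique record ids.
#' @param sequence nucleotide sequences.
#' @param quality optional per-base quality strings (same lengths as
#'   `sequence`).
#' @param dupcount integer duplicate counts, recycled.
#' @return a `data.frame` of sequence records.
#' @export
seq_records <- function(id, sequence, quality = NA_character_, dupcount = 1L) {
  sequence <- .norm_seq(as.character(sequence))
  .check_dna(sequence, allow_n = TRUE)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  quality <- rep_len(as.character(quality), length(id))
  has_q <- !is.na(quality)
  if (any(has_q & nchar(quality) != nchar(sequence)))
    stop("quality length differs from sequence length for record ",
         id[which(has_q & nchar(quality) != nchar(sequence))[1]])
  dupcount <- rep_len(as.integer(dupcount), length(id))
  if (any(dupcount < 1L)) stop("dupcount must be >= 1")
  data.frame(id = id, sequence = sequence, quality = quality,
             dupcount = dupcount, stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (by extension, falling back
#'   to sniffing the first character).
#' @return a sequence-record table (see [seq_records()]); `dupcount` is
#'   initialized to 1 and FASTQ qualities are retained.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq"
    else if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) "fasta"
    else if (identical(substr(readLines(path, n = 1L), 1L, 1L), "@")) "fastq"
    else "fasta"
  }
  if (format == "fasta") {
    .validate_fasta_lines(path)
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- NA_character_
  } else {
    .validate_fastq_lines(path)
    x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  }
  ids <- sub("\\s.*$", "", names(x))
  seq_records(id = ids, sequence = as.character(x), quality = qual, dupcount = 1L)
}

# Light structural validators so malformed records fail with the offending
# line named (Biostrings' own messages do not carry line numbers).
.validate_fasta_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || substr(lines[1], 1, 1) != ">")
    stop("malformed FASTA in ", path, ": line 1 does not start with '>'")
  invisible(TRUE)
}

.validate_fastq_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": line count not a multiple of 4")
  n <- length(lines) %/% 4L
  for (r in seq_len(n)) {
    b <- (r - 1L) * 4L
    if (substr(lines[b + 1L], 1, 1) != "@")
      stop("malformed FASTQ in ", path, ": line ", b + 1L, " does not start with '@'")
    if (substr(lines[b + 3L], 1, 1) != "+")
      stop("malformed FASTQ in ", path, ": line ", b + 3L, " does not start with '+'")
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L]))
      stop("malformed FASTQ in ", path, ": quality length differs from sequence ",
           "length at line ", b + 4L)
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records a sequence-record table.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on every
#'   record.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  } else {
    if (anyNA(records$quality))
      stop("FASTQ output requires qualities on every record")
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(records$quality))
  }
  invisible(path)
}

## ---------------------------------------------------------------- germline sets

#' Construct a germline allele set
#'
#' A germline set holds the de-duplicated V and/or J alleles of one strain at
#' one locus. Alleles with identical `(segment, sequence)` are collapsed (the
#' number of collapsed entries is kept in attribute `n_collapsed`) and the
#' set is ordered by name so output is byte-stable.
#'
#' @param name allele labels, unique within the set after collapsing.
#' @param sequence nucleotide sequences (strictly A/C/G/T).
#' @param segment `"V"` or `"J"` per allele, recycled.
#' @param locus one of `"IGH"`, `"IGK"`, `"IGL"`.
#' @param strain optional strain label.
#' @param status `"reference"`, `"inferred-known"` or `"inferred-novel"`,
#'   recycled.
#' @return an object of class `germline_set` (a data.frame).
#' @export
germline_set <- function(name, sequence, segment = "V", locus = "IGK",
                         strain = NA_character_, status = "reference") {
  locus <- match.arg(locus, c("IGH", "IGK", "IGL"))
  sequence <- .norm_seq(as.character(sequence))
  if (any(!nzchar(sequence))) stop("allele sequences must be non-empty")
  .check_dna(sequence, allow_n = FALSE, what = "allele")
  segment <- rep_len(match.arg(segment, c("V", "J"), several.ok = TRUE), length(name))
  status <- rep_len(status, length(name))
  if (!all(status %in% c("reference", "inferred-known", "inferred-novel")))
    stop("invalid allele status")
  df <- data.frame(name = as.character(name), locus = locus, segment = segment,
                   sequence = sequence, strain = strain, status = status,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("segment", "sequence")])
  n_collapsed <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  if (anyDuplicated(df$name))
    stop("duplicate allele names in germline set: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  df <- df[order(df$name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("germline_set", "data.frame"),
            strain = strain[1], locus = locus, n_collapsed = n_collapsed)
}

#' @export
print.germline_set <- function(x, ...) {
  cat("Germline set: ", attr(x, "locus"),
      if (!is.na(attr(x, "strain"))) paste0(" (", attr(x, "strain"), ")"),
      " -- ", sum(x$segment == "V"), " V, ", sum(x$segment == "J"),
      " J alleles\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[, c("name", "segment", "status")], 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Read a germline set from FASTA
#'
#' @inheritParams germline_set
#' @param path FASTA file of allele sequences.
#' @export
read_germline_fasta <- function(path, segment = "V", locus = "IGK",
                                strain = NA_character_, status = "reference") {
  rec <- read_sequences(path, format = "fasta")
  germline_set(rec$id, rec$sequence, segment = segment, locus = locus,
               strain = strain, status = status)
}

#' Write a germline set to FASTA
#' @param set a `germline_set`.
#' @param path output path.
#' @export
write_germline_fasta <- function(set, path) {
  write_sequences(data.frame(id = set$name, sequence = set$sequence,
                             quality = NA_character_, dupcount = 1L),
                  path, format = "fasta")
}

## ------------------------------------------------------------- rearrangements

REARRANGEMENT_COLS <- c("sequence_id", "sequence", "v_call", "j_call",
                        "v_identity", "v_start", "v_end", "j_start", "j_end",
                        "j_region", "clone_id", "dupcount")

#' Construct a rearrangement table
#'
#' Rearrangements are annotated reads with V/J calls. Coordinates are 0-based
#' half-open on the read; `j_call` is `""` when no J was assigned, and the
#' corresponding coordinates are `NA`.
#'
#' @param sequence_id,sequence read id and nucleotide sequence.
#' @param v_call,j_call allele names (`j_call` may be `""`).
#' @param v_identity percent identity of the V alignment, in `[0, 100]`.
#' @param v_start,v_end,j_start,j_end 0-based half-open alignment coordinates
#'   on the read.
#' @param j_region read substring used for J analysis.
#' @param clone_id optional clone label.
#' @param dupcount duplicate count (>= 1).
#' @return a `data.frame` with the rearrangement columns.
#' @export
rearrangements <- function(sequence_id, sequence, v_call, j_call = "",
                           v_identity = NA_real_, v_start = NA_integer_,
                           v_end = NA_integer_, j_start = NA_integer_,
                           j_end = NA_integer_, j_region = "",
                           clone_id = NA_character_, dupcount = 1L) {
  n <- length(sequence_id)
  df <- data.frame(sequence_id = as.character(sequence_id),
                   sequence = .norm_seq(as.character(sequence)),
                   v_call = as.character(v_call),
                   j_call = rep_len(as.character(j_call), n),
                   v_identity = rep_len(as.numeric(v_identity), n),
                   v_start = rep_len(as.integer(v_start), n),
                   v_end = rep_len(as.integer(v_end), n),
                   j_start = rep_len(as.integer(j_start), n),
                   j_end = rep_len(as.integer(j_end), n),
                   j_region = rep_len(as.character(j_region), n),
                   clone_id = rep_len(as.character(clone_id), n),
                   dupcount = rep_len(as.integer(dupcount), n),
                   stringsAsFactors = FALSE)
  validate_rearrangements(df)
}

#' Validate rearrangement invariants
#' @param df a rearrangement table.
#' @return `df`, invisibly checked.
#' @export
validate_rearrangements <- function(df) {
  miss <- setdiff(REARRANGEMENT_COLS, names(df))
  if (length(miss)) stop("missing rearrangement columns: ", paste(miss, collapse = ", "))
  len <- nchar(df$sequence)
  ok_v <- is.na(df$v_start) | (df$v_start >= 0L & df$v_start < df$v_end & df$v_end <= len)
  if (!all(ok_v)) stop("invalid V coordinates for ",
                       df$sequence_id[which(!ok_v)[1]])
  has_j <- !is.na(df$j_start)
  ok_j <- !has_j | (df$j_start >= df$v_end & df$j_end <= len & df$j_start < df$j_end)
  if (!all(ok_j)) stop("invalid J coordinates (J interval must not precede v_end) for ",
                       df$sequence_id[which(!ok_j)[1]])
  ok_id <- is.na(df$v_identity) | (df$v_identity >= 0 & df$v_identity <= 100)
  if (!all(ok_id)) stop("v_identity out of [0, 100] for ",
                        df$sequence_id[which(!ok_id)[1]])
  if (any(df$dupcount < 1L)) stop("dupcount must be >= 1")
  df
}

#' Read an AIRR Rearrangement TSV
#'
#' The on-disk dialect uses 1-based inclusive `*_sequence_start`/`*_sequence_end`
#' coordinates, which are converted to the internal 0-based half-open
#' convention.
#'
#' @param path TSV path with a header line.
#' @return a rearrangement table.
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = character())
  required <- c("sequence_id", "sequence", "v_call", "j_call")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("AIRR table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  num <- function(col, default = NA_real_) {
    if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]]))
    else rep(default, nrow(df))
  }
  get <- function(col, default = "") {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  if (nrow(df) == 0L) {
    return(rearrangements(character(), character(), character()))
  }
  rearrangements(
    sequence_id = df$sequence_id, sequence = df$sequence,
    v_call = df$v_call, j_call = get("j_call"),
    v_identity = num("v_identity"),
    v_start = as.integer(num("v_sequence_start")) - 1L,
    v_end = as.integer(num("v_sequence_end")),
    j_start = as.integer(num("j_sequence_start")) - 1L,
    j_end = as.integer(num("j_sequence_end")),
    j_region = get("j_region"),
    clone_id = {x <- get("clone_id", NA_character_); x[x == ""] <- NA; x},
    dupcount = {x <- suppressWarnings(as.integer(get("dupcount", "1"))); x[is.na(x)] <- 1L; x})
}

#' Write an AIRR Rearrangement TSV
#' @param df a rearrangement table (internal 0-based half-open coordinates).
#' @param path output path.
#' @export
write_airr <- function(df, path) {
  validate_rearrangements(df)
  out <- data.frame(sequence_id = df$sequence_id, sequence = df$sequence,
                    v_call = df$v_call, j_call = df$j_call,
                    v_identity = df$v_identity,
                    v_sequence_start = df$v_start + 1L,
                    v_sequence_end = df$v_end,
                    j_sequence_start = df$j_start + 1L,
                    j_sequence_end = df$j_end,
                    j_region = df$j_region,
                    clone_id = ifelse(is.na(df$clone_id), "", df$clone_id),
                    dupcount = df$dupcount,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

## -------------------------------------------------------------- SNP genotypes

#' Construct a strain-by-position genotype matrix
#'
#' @param genotypes character matrix over `{A, C, G, T, N}` with strains as
#'   rows (rownames) and locus positions as columns (colnames optional).
#' @param mask optional logical per-position mask (defaults to all FALSE).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, mask = NULL) {
  if (!is.matrix(genotypes) || !is.character(genotypes))
    stop("genotypes must be a character matrix")
  if (is.null(rownames(genotypes))) stop("genotype matrix requires strain rownames")
  if (!all(genotypes %in% c("A", "C", "G", "T", "N")))
    stop("genotypes must be single characters in {A, C, G, T, N} ",
         "(heterozygous codes are rejected; inbred strains are assumed homozygous)")
  if (is.null(mask)) mask <- rep(FALSE, ncol(genotypes))
  if (length(mask) != ncol(genotypes))
    stop("mask length must equal the number of positions")
  structure(list(genotypes = genotypes, mask = as.logical(mask)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$genotypes), " strains x ",
      ncol(x$genotypes), " positions (", sum(x$mask), " masked)\n", sep = "")
  invisible(x)
}

#' Read/write a genotype matrix as TSV (strains in the first column)
#' @param path TSV path.
#' @rdname genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genotype_matrix(m)
}

#' @param gm a `genotype_matrix`.
#' @rdname genotype_tsv
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(strain = rownames(gm$genotypes), gm$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------- trees

#' Height of a rooted tree
#'
#' Maximum root-to-leaf path length of an ape `phylo` tree (the quantity used
#' as the reference height when extracting family subtrees).
#'
#' @param tree an ape `phylo` object with edge lengths.
#' @return numeric height.
#' @export
tree_height <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))])
}
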