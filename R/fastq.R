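#' Emit paired FASTQ reads from an interaction table
#'
#' For every counted primer pair, writes that many read pairs. Mate 1
#' carries the T7 tail, the forward primer, the EcoRI ligation junction and
#' the (truncated) reverse primer; mate 2 carries the T3 tail, the reverse
#' primer, the junction and the forward primer. Decoy pairs (unmatchable
#' random sequence, chimeric/ambiguous junctions, or low-quality signal
#' reads) can replace a configurable fraction of signal pairs so the
#' quantifier's discard paths are exercisable.
#'
#' @param table an [interaction_table()] of raw counts.
#' @param primers the `primer_set` the table refers to.
#' @param fastq1,fastq2 output paths (mate 1 / mate 2), Phred+33.
#' @param seed integer seed.
#' @param decoy_fraction fraction of emitted pairs converted to decoys
#'   (1.0 means every pair is a decoy and nothing is assignable).
#' @param low_quality_fraction fraction of the remaining signal pairs whose
#'   quality strings are degraded (see `low_quality_base_fraction`).
#' @param low_quality_base_fraction fraction of bases set to Q2 in degraded
#'   reads; 0.3 drops a read below the 80%-at-Q25 filter.
#' @param read_length output read length in bp.
#' @param base_quality default per-base Phred score.
#' @return invisibly, a list with `n_pairs`, `n_decoys`, `n_low_quality`
#'   and the output paths.
#' @export
emit_read_pairs <- function(table, primers, fastq1, fastq2, seed = 1L,
                            decoy_fraction = 0,
                            low_quality_fraction = 0,
                            low_quality_base_fraction = 0.3,
                            read_length = 100L,
                            base_quality = 40L) {
  stopifnot(inherits(table, "interaction_table"))
  validate_primer_set(primers)
  if (any(table$raw_count < 0)) stop("counts must be non-negative")
  set.seed(derive_seed(seed, 7L))

  idx <- rep(seq_len(nrow(table)), times = table$raw_count)
  n <- length(idx)
  seq_by_id <- stats::setNames(primers$sequence, primers$id)
  fwd_seq <- unname(seq_by_id[table$fwd_id[idx]])
  rev_seq <- unname(seq_by_id[table$rev_id[idx]])

  r1 <- pad_read(paste0(PRIMER_TAILS[["T7"]], fwd_seq, JUNCTION_MOTIF, rev_seq),
                 read_length)
  r2 <- pad_read(paste0(PRIMER_TAILS[["T3"]], rev_seq, JUNCTION_MOTIF, fwd_seq),
                 read_length)

  q1 <- rep(strrep(phred_char(base_quality), read_length), n)
  q2 <- q1

  n_decoy <- round(decoy_fraction * n)
  decoy_at <- if (n_decoy > 0) sort(sample.int(n, n_decoy)) else integer(0)
  fwd_ids <- primers$id[primers$orientation == "forward"]
  rev_ids <- primers$id[primers$orientation == "reverse"]
  for (j in seq_along(decoy_at)) {
    i <- decoy_at[j]
    kind <- j %% 3L
    if (kind == 1L || length(fwd_ids) < 1L || length(rev_ids) < 2L) {
      # unmatchable: random sequence in both mates
      r1[i] <- random_dna(read_length)
      r2[i] <- random_dna(read_length)
    } else if (kind == 2L) {
      # chimeric: the two mates point to conflicting reverse primers
      f <- sample(fwd_ids, 1L)
      rr <- sample(rev_ids, 2L)
      r1[i] <- pad_read(paste0(PRIMER_TAILS[["T7"]], seq_by_id[[f]],
                               JUNCTION_MOTIF, seq_by_id[[rr[1L]]]),
                        read_length)
      r2[i] <- pad_read(paste0(PRIMER_TAILS[["T3"]], seq_by_id[[rr[2L]]],
                               JUNCTION_MOTIF, seq_by_id[[f]]),
                        read_length)
    } else {
      # low-quality signal: sequence intact, qualities below the filter
      q1[i] <- degrade_quality(q1[i], 0.3)
      q2[i] <- degrade_quality(q2[i], 0.3)
    }
  }

  if (low_quality_fraction > 0) {
    signal <- setdiff(seq_len(n), decoy_at)
    n_lq <- round(low_quality_fraction * length(signal))
    lq_at <- if (n_lq > 0) sample(signal, n_lq) else integer(0)
    for (i in lq_at) {
      q1[i] <- degrade_quality(q1[i], low_quality_base_fraction)
      q2[i] <- degrade_quality(q2[i], low_quality_base_fraction)
    }
  } else {
    lq_at <- integer(0)
  }

  ids <- sprintf("read_%06d", seq_len(n))
  write_fastq(ids, r1, q1, fastq1)
  write_fastq(ids, r2, q2, fastq2)
  invisible(list(n_pairs = n, n_decoys = n_decoy,
                 n_low_quality = length(lq_at),
                 fastq1 = fastq1, fastq2 = fastq2))
}

pad_read <- function(x, read_length) {
  short <- nchar(x) < read_length
  if (any(short))
    x[short] <- paste0(x[short],
                       vapply(read_length - nchar(x[short]), random_dna,
                              character(1)))
  substr(x, 1L, read_length)
}

random_dna <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

phred_char <- function(q) rawToChar(as.raw(q + 33L))

# Set a fraction of bases (chosen at random) to Q2.
degrade_quality <- function(qual, fraction) {
  v <- strsplit(qual, "")[[1L]]
  k <- round(fraction * length(v))
  if (k > 0) v[sample.int(length(v), k)] <- phred_char(2L)
  paste(v, collapse = "")
}

write_fastq <- function(ids, seqs, quals, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  qual <- Biostrings::BStringSet(quals)
  ok <- tryCatch({
    Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                                qualities = qual)
    TRUE
  }, error = function(e) {
    stop("failed writing FASTQ to ", path, ": ", conditionMessage(e))
  })
  invisible(ok)
}

#' Read a pair of FASTQ files into a read-pair frame
#'
#' @param fastq1,fastq2 mate file paths (Phred+33).
#' @return data.frame of class `read_pairs` with columns `id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  for (p in c(fastq1, fastq2))
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
  m1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq",
                                     with.qualities = TRUE)
  m2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(m1) != length(m2))
    stop("mate files differ in read count")
  pairs <- data.frame(
    id = names(m1),
    seq1 = as.character(m1),
    qual1 = as.character(S4Vectors::mcols(m1)$qualities),
    seq2 = as.character(m2),
    qual2 = as.character(S4Vectors::mcols(m2)$qualities),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(pairs, trimmed = FALSE, class = c("read_pairs", "data.frame"))
}
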