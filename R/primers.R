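#' Universal primer tails
#'
#' The universal overhangs carried by 5C primers: forward primers carry the
#' T7 sequence, reverse primers the T3 sequence. Amplification of ligated
#' junctions uses these two universal sequences.
#' @format Named character vector with elements `T7` and `T3`.
#' @export
PRIMER_TAILS <- c(
  T7 = "TAATACGACTCACTATAGCC",
  T3 = "TATTAACCCTCACTAAAGGGA")

#' Restriction-site ligation junction motif
#' @format Character scalar (EcoRI recognition sequence).
#' @export
JUNCTION_MOTIF <- "GAATTC"

#' Generate an alternating forward/reverse 5C primer set
#'
#' Tiles primers along each chromosome every `spacing` bp in the alternating
#' design: odd positions get forward (T7-tailed) primers, even positions
#' reverse (T3-tailed) primers. Each primer receives a unique random 30-mer
#' genomic sequence, reproducible from the genome seed.
#'
#' @param genome a [toy_genome()].
#' @param spacing distance between consecutive primer anchors in bp
#'   (>= 1000).
#' @param primer_length genomic sequence length per primer (default 30, the
#'   optimal primer size used in 5C designs).
#' @return data.frame of class `primer_set` with columns `id`, `chrom`,
#'   `start`, `end` (0-based half-open), `orientation`, `tail`, `sequence`.
#' @export
generate_primer_set <- function(genome, spacing = 10000, primer_length = 30L) {
  stopifnot(inherits(genome, "toy_genome"))
  if (spacing < 1000) stop("spacing must be >= 1 kb")
  out <- list()
  set.seed(derive_seed(genome$seed, 1L))
  for (ch in genome$chrom_names) {
    len <- genome$chrom_lengths[[ch]]
    if (spacing > len) {
      warning("spacing exceeds length of ", ch, "; no primers placed")
      next
    }
    starts <- seq(0, len - primer_length, by = spacing)
    n <- length(starts)
    if (n == 0L) next
    fwd <- seq_len(n) %% 2L == 1L
    seqs <- unique_random_kmers(n, primer_length)
    out[[ch]] <- data.frame(
      id = sprintf("%s_%s_%03d", ch,
                   ifelse(fwd, "FOR", "REV"), seq_len(n)),
      chrom = ch,
      start = starts,
      end = starts + primer_length,
      orientation = ifelse(fwd, "forward", "reverse"),
      tail = ifelse(fwd, "T7", "T3"),
      sequence = seqs,
      stringsAsFactors = FALSE)
  }
  primers <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  else
    data.frame(id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          orientation = character(), tail = character(),
                          sequence = character(), stringsAsFactors = FALSE)
  class(primers) <- c("primer_set", "data.frame")
  validate_primer_set(primers)
  primers
}

# Draw n distinct random DNA k-mers under the current RNG state.
unique_random_kmers <- function(n, k) {
  seqs <- character(0)
  while (length(seqs) < n) {
    more <- vapply(seq_len(n - length(seqs)), function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
    seqs <- unique(c(seqs, more))
  }
  seqs
}

validate_primer_set <- function(primers) {
  stopifnot(is.data.frame(primers))
  need <- c("id", "chrom", "start", "end", "orientation", "tail", "sequence")
  if (!all(need %in% names(primers)))
    stop("primer set missing columns: ",
         paste(setdiff(need, names(primers)), collapse = ", "))
  if (anyDuplicated(primers$sequence))
    stop("primer sequences must be unique")
  if (any(primers$end <= primers$start))
    stop("primer end must exceed start")
  bad <- (primers$orientation == "forward" & primers$tail != "T7") |
         (primers$orientation == "reverse" & primers$tail != "T3")
  if (any(bad))
    stop("forward primers must carry the T7 tail, reverse the T3 tail")
  invisible(primers)
}

#' Write / read a primer table as TSV
#'
#' Plain-TSV serialization of a primer set. Coordinates are written 0-based
#' half-open; `dialect = "one_based"` on read converts 1-based inclusive
#' input tables.
#'
#' @param primers a `primer_set` data.frame.
#' @param path file path.
#' @param dialect coordinate convention of the file being read.
#' @return `read_primer_table` returns a `primer_set`.
#' @export
write_primer_table <- function(primers, path) {
  validate_primer_set(primers)
  data.table::fwrite(as.data.frame(primers), path, sep = "\t")
  invisible(path)
}

#' @rdname write_primer_table
#' @export
read_primer_table <- function(path, dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  primers <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (dialect == "one_based") {
    primers$start <- primers$start - 1L
  }
  class(primers) <- c("primer_set", "data.frame")
  validate_primer_set(primers)
  primers
}
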