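#' Trim the universal-tail and low-quality ends off read pairs
#'
#' All 5C reads share common ends (universal tails 5', primer runoff 3'),
#' so a fixed trim is applied: bases 1 to `five_prime_cut` and bases from
#' `three_prime_from` onwards are removed (1-based inclusive), keeping the
#' window `five_prime_cut + 1 .. three_prime_from - 1`. Quality strings are
#' trimmed identically. Pairs whose reads are too short to retain anything
#' are dropped and counted.
#'
#' @param pairs a `read_pairs` frame from [read_fastq_pairs()].
#' @param five_prime_cut number of 5' bases removed (default 20).
#' @param three_prime_from first 3' base removed, 1-based (default 80).
#' @return trimmed `read_pairs`; attribute `n_short_dropped` counts dropped
#'   pairs. Trimming an already-trimmed frame is an error.
#' @export
trim_reads <- function(pairs, five_prime_cut = 20L, three_prime_from = 80L) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (isTRUE(attr(pairs, "trimmed")))
    stop("read pairs are already trimmed (idempotence guard)")
  if (five_prime_cut < 1L || five_prime_cut > 20L)
    stop("five_prime_cut must lie in 1..20")
  if (three_prime_from < 80L || three_prime_from > 100L)
    stop("three_prime_from must lie in 80..100")
  keep_from <- five_prime_cut + 1L
  keep_to <- three_prime_from - 1L
  ok <- nchar(pairs$seq1) >= keep_from & nchar(pairs$seq2) >= keep_from
  n_short <- sum(!ok)
  out <- pairs[ok, , drop = FALSE]
  for (col in c("seq1", "qual1", "seq2", "qual2"))
    out[[col]] <- substr(out[[col]], keep_from, keep_to)
  rownames(out) <- NULL
  structure(out, trimmed = TRUE, n_short_dropped = n_short,
            class = class(pairs))
}

#' Phred-score filter for read pairs
#'
#' A pair is kept iff, in *both* mates, the fraction of bases with Phred
#' score >= `min_phred` is >= `min_fraction` (both bounds inclusive).
#'
#' @param pairs a `read_pairs` frame (Phred+33 qualities).
#' @param min_phred minimum qualifying base quality (default 25).
#' @param min_fraction minimum fraction of qualifying bases (default 0.80).
#' @return list with `kept` (the surviving `read_pairs`), `keep` (logical
#'   per input pair) and `n_dropped`.
#' @export
quality_filter <- function(pairs, min_phred = 25L, min_fraction = 0.80) {
  stopifnot(inherits(pairs, "read_pairs"))
  frac_ok <- function(qual) {
    vapply(qual, function(q) {
      ph <- utf8ToInt(q) - 33L
      if (length(ph) == 0L) return(0)
      mean(ph >= min_phred)
    }, numeric(1), USE.NAMES = FALSE)
  }
  keep <- frac_ok(pairs$qual1) >= min_fraction &
          frac_ok(pairs$qual2) >= min_fraction
  kept <- pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attributes(kept)[c("trimmed")] <- attributes(pairs)[c("trimmed")]
  class(kept) <- class(pairs)
  list(kept = kept, keep = keep, n_dropped = sum(!keep))
}

#' Assign read pairs to forward x reverse primer combinations
#'
#' Matches each read pair against the catalog of primer junction sequences
#' by exact substring search (0 mismatches). A mate identifies its own
#' primer by a full match and, where the ligation junction motif follows,
#' the mate primer by its prefix — so a single confident mate suffices to
#' credit a pair. Pairs resolving to exactly one forward x reverse
#' combination increment that pair's count; pairs matching two or more
#' combinations are discarded as multi-mapping, pairs matching none as
#' unmatched, and both are tallied.
#'
#' @param pairs trimmed, quality-filtered `read_pairs`.
#' @param primers the `primer_set` catalog (unique sequences).
#' @param min_mate_bases minimum junction-spanning bases needed to call the
#'   mate primer from a prefix (default 15).
#' @param junction ligation junction motif between the two primers.
#' @return an [interaction_table()] of raw counts; attribute `tallies`
#'   holds the assigned/ambiguous/unmatched bookkeeping.
#' @export
assign_primer_pairs <- function(pairs, primers, min_mate_bases = 15L,
                                junction = JUNCTION_MOTIF) {
  stopifnot(inherits(pairs, "read_pairs"))
  validate_primer_set(primers)
  n <- nrow(pairs)
  pl <- nchar(primers$sequence)
  jl <- nchar(junction)

  # full-match positions of every primer in every mate
  hits <- list()
  for (mate in 1:2) {
    seqs <- pairs[[paste0("seq", mate)]]
    for (k in seq_len(nrow(primers))) {
      pos <- as.integer(regexpr(primers$sequence[k], seqs, fixed = TRUE))
      at <- which(pos > 0L)
      if (length(at))
        hits[[length(hits) + 1L]] <-
          data.frame(read = at, mate = mate, primer = k, pos = pos[at])
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(read = integer(), mate = integer(),
               primer = integer(), pos = integer())

  combos_of_read <- vector("list", n)
  full_by_read <- split(seq_len(nrow(hits)), factor(hits$read, seq_len(n)))
  for (i in seq_len(n)) {
    hrows <- full_by_read[[i]]
    if (length(hrows) == 0L) next
    h <- hits[hrows, , drop = FALSE]
    combos <- character(0)
    fwd_full <- unique(h$primer[primers$orientation[h$primer] == "forward"])
    rev_full <- unique(h$primer[primers$orientation[h$primer] == "reverse"])
    if (length(fwd_full) && length(rev_full))
      combos <- c(combos, paste(rep(fwd_full, each = length(rev_full)),
                                rev_full, sep = "|"))
    # prefix resolution of the mate primer across the junction motif
    for (r in seq_len(nrow(h))) {
      k <- h$primer[r]
      s <- pairs[[paste0("seq", h$mate[r])]][i]
      e <- h$pos[r] + pl[k] - 1L
      if (substr(s, e + 1L, e + jl) != junction) next
      partial <- substr(s, e + jl + 1L, nchar(s))
      if (nchar(partial) < min_mate_bases) next
      opp <- if (primers$orientation[k] == "forward") "reverse" else "forward"
      cand <- which(primers$orientation == opp)
      cmplen <- pmin(nchar(partial), pl[cand])
      match <- cand[substr(primers$sequence[cand], 1L, cmplen) ==
                      substr(partial, 1L, cmplen)]
      if (length(match) >= 1L) {
        key <- if (opp == "reverse") paste(k, match, sep = "|")
               else paste(match, k, sep = "|")
        combos <- c(combos, key)
      }
    }
    combos_of_read[[i]] <- unique(combos)
  }

  n_combos <- lengths(combos_of_read)
  assigned <- which(n_combos == 1L)
  tallies <- list(assigned = length(assigned),
                  ambiguous = sum(n_combos > 1L),
                  unmatched = sum(n_combos == 0L),
                  quality_dropped = 0L,
                  short_dropped = 0L)

  counts <- table(unlist(combos_of_read[assigned]))
  if (length(counts)) {
    ix <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
    records <- data.frame(
      fwd_id = primers$id[as.integer(ix[, 1L])],
      rev_id = primers$id[as.integer(ix[, 2L])],
      raw_count = as.integer(counts),
      stringsAsFactors = FALSE)
    records <- records[order(records$fwd_id, records$rev_id), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- data.frame(fwd_id = character(), rev_id = character(),
                          raw_count = integer(), stringsAsFactors = FALSE)
  }
  interaction_table(records, total_mapped = length(assigned),
                    tallies = tallies)
}

#' Quantify a paired 5C FASTQ into a normalized interaction table
#'
#' Convenience pipeline: read, trim, Phred-filter, assign primer pairs and
#' total-count normalize, with complete count conservation bookkeeping
#' (assigned + ambiguous + unmatched + quality_dropped + short_dropped =
#' input pairs).
#'
#' @param fastq1,fastq2 mate FASTQ paths.
#' @param primers `primer_set` catalog.
#' @param norm_factor total-count normalization factor (data-derived
#'   calibration constant; e.g. published 5C analyses used 11.62 / 8.65 for
#'   their control / experiment libraries).
#' @param min_phred,min_fraction quality-filter settings.
#' @param five_prime_cut,three_prime_from trim window, see [trim_reads()].
#' @return a normalized [interaction_table()].
#' @export
quantify_fivec <- function(fastq1, fastq2, primers, norm_factor = 1,
                           min_phred = 25L, min_fraction = 0.80,
                           five_prime_cut = 20L, three_prime_from = 80L) {
  pairs <- read_fastq_pairs(fastq1, fastq2)
  n_input <- nrow(pairs)
  trimmed <- trim_reads(pairs, five_prime_cut, three_prime_from)
  qf <- quality_filter(trimmed, min_phred, min_fraction)
  tab <- assign_primer_pairs(qf$kept, primers)
  tl <- attr(tab, "tallies")
  tl$quality_dropped <- qf$n_dropped
  tl$short_dropped <- attr(trimmed, "n_short_dropped")
  tl$input_pairs <- n_input
  attr(tab, "tallies") <- tl
  normalize_total(tab, norm_factor)
}
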