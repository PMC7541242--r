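# Independent oracles and shared fixtures for the test suite.

# Naive double-loop Directionality Index: direct evaluation of
# DI = sign(B - A) * ((A-E)^2/E + (B-E)^2/E), E = (A+B)/2.
naive_di <- function(values, bin_starts, window) {
  v <- values
  v[is.na(v)] <- 0
  n <- length(bin_starts)
  di <- numeric(n)
  for (i in seq_len(n)) {
    A <- 0
    B <- 0
    for (j in seq_len(n)) {
      d <- bin_starts[i] - bin_starts[j]
      if (d > 0 && d <= window) A <- A + v[i, j]
      if (d < 0 && -d <= window) B <- B + v[i, j]
    }
    E <- (A + B) / 2
    di[i] <- if (A == B) 0 else
      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  di
}

# Random symmetric contact matrix with missing cells.
random_contact_matrix <- function(n_bins, bin_size = 10000,
                                  na_fraction = 0.2) {
  m <- matrix(NA_real_, n_bins, n_bins)
  ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  vals <- round(stats::rexp(nrow(ut), rate = 0.1), 3)
  vals[stats::runif(nrow(ut)) < na_fraction] <- NA
  m[ut] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix("toy", bin_size, bin_size,
                 seq(0, by = bin_size, length.out = n_bins), m, "raw")
}

# Brute-force 1-D single-linkage clustering via hclust, returning the
# median position of clusters supported by >= min_support replicates.
oracle_consensus <- function(positions, replicates, tolerance,
                             min_support = 2L) {
  if (length(positions) == 1L) {
    if (length(unique(replicates)) >= min_support) return(positions)
    return(numeric(0))
  }
  hc <- stats::hclust(stats::dist(positions), method = "single")
  cl <- stats::cutree(hc, h = tolerance)
  out <- numeric(0)
  for (g in unique(cl)) {
    if (length(unique(replicates[cl == g])) >= min_support)
      out <- c(out, stats::median(positions[cl == g]))
  }
  sort(out)
}

# Build a tad_set from a sorted vector of boundary positions by pairing
# them into consecutive, non-overlapping domains.
tad_set_from_positions <- function(positions, chrom = "c", replicate = 1L) {
  positions <- sort(positions)
  k <- length(positions) %/% 2L
  if (k == 0L) stop("need >= 2 positions")
  tads <- data.frame(chrom = chrom,
                     start = positions[seq(1, 2 * k, by = 2)],
                     end = positions[seq(2, 2 * k, by = 2)],
                     replicate = replicate)
  tad_set(tads, data.frame(chrom = character(), start = numeric(),
                           end = numeric()))
}

# Small shared fixtures.
fixture_genome <- function(seed = 1L, len = 1e6) {
  toy_genome(chrom_names = "chr2L_het", chrom_lengths = len, seed = seed)
}

fixture_model <- function(...) {
  planted_tad_model(default_tad_layout(), ...)
}

# Read-pairs frame built directly in code (bypasses FASTQ round trip).
make_read_pairs <- function(seq1, qual1 = strrep("I", nchar(seq1)),
                            seq2 = seq1,
                            qual2 = strrep("I", nchar(seq2))) {
  structure(data.frame(id = sprintf("r%03d", seq_along(seq1)),
                       seq1 = seq1, qual1 = qual1,
                       seq2 = seq2, qual2 = qual2,
                       stringsAsFactors = FALSE),
            trimmed = FALSE, class = c("read_pairs", "data.frame"))
}
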