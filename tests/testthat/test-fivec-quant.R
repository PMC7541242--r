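test_that("trimming keeps bases 21-79 and guards idempotence", {
  read <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  qual <- paste(rep(c("I", "J"), 50), collapse = "")
  rp <- make_read_pairs(read, qual)
  tr <- trim_reads(rp)
  # brute-force slicing oracle for the printed 1-20 / 80-100 ranges
  expect_equal(tr$seq1, substr(read, 21, 79))
  expect_equal(tr$qual1, substr(qual, 21, 79))
  expect_equal(nchar(tr$seq1), 59L)
  expect_error(trim_reads(tr), "already trimmed")

  short <- make_read_pairs(strrep("A", 20))
  tr2 <- trim_reads(short)
  expect_equal(nrow(tr2), 0L)
  expect_equal(attr(tr2, "n_short_dropped"), 1L)
})

test_that("Phred filter uses inclusive >= bounds on both mates", {
  q30 <- het5c:::phred_char(30)
  q2 <- het5c:::phred_char(2)
  q25 <- het5c:::phred_char(25)
  mk <- function(q) make_read_pairs(strrep("A", 100), q)

  # 85 of 100 bases at Q30 -> keep (recount: 0.85 >= 0.80)
  qual <- paste0(strrep(q30, 85), strrep(q2, 15))
  expect_true(quality_filter(mk(qual))$keep)
  # all bases Q2 -> drop
  expect_false(quality_filter(mk(strrep(q2, 100)))$keep)
  # exactly 80% at exactly Q25 -> keep (both boundaries inclusive)
  qual <- paste0(strrep(q25, 80), strrep(q2, 20))
  expect_true(quality_filter(mk(qual))$keep)
  # one bad mate drops the pair
  good <- strrep(q30, 100)
  rp <- make_read_pairs(strrep("A", 100), good,
                        strrep("A", 100), strrep(q2, 100))
  expect_false(quality_filter(rp)$keep)
})

test_that("primer-pair assignment resolves unique combinations only", {
  g <- toy_genome(chrom_lengths = 2e5, seed = 21)
  p <- generate_primer_set(g, spacing = 10000)
  fwd <- p$sequence[p$orientation == "forward"]
  rev <- p$sequence[p$orientation == "reverse"]
  fid <- p$id[p$orientation == "forward"]
  rid <- p$id[p$orientation == "reverse"]
  J <- JUNCTION_MOTIF

  # clean junction pair built from primers (F3, R7)
  s1 <- substr(paste0(fwd[3], J, rev[7], strrep("A", 40)), 1, 59)
  s2 <- substr(paste0(rev[7], J, fwd[3], strrep("A", 40)), 1, 59)
  rp <- make_read_pairs(s1, seq2 = s2)
  attr(rp, "trimmed") <- TRUE
  tab <- assign_primer_pairs(rp, p)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$fwd_id, fid[3])
  expect_equal(tab$rev_id, rid[7])
  expect_equal(tab$raw_count, 1L)

  # a read containing two different forward primers is multi-mapping
  s1 <- substr(paste0(fwd[1], fwd[2]), 1, 60)
  rp <- make_read_pairs(s1, seq2 = substr(paste0(rev[1], J, fwd[1]), 1, 59))
  attr(rp, "trimmed") <- TRUE
  tab <- assign_primer_pairs(rp, p)
  expect_equal(attr(tab, "tallies")$ambiguous, 1L)
  expect_equal(nrow(tab), 0L)

  # unmatchable read
  rp <- make_read_pairs(strrep("A", 59))
  attr(rp, "trimmed") <- TRUE
  tab <- assign_primer_pairs(rp, p)
  expect_equal(attr(tab, "tallies")$unmatched, 1L)
})

test_that("a single confident mate suffices to credit a pair", {
  g <- toy_genome(chrom_lengths = 2e5, seed = 22)
  p <- generate_primer_set(g, spacing = 10000)
  fwd <- p$sequence[p$orientation == "forward"]
  rev <- p$sequence[p$orientation == "reverse"]
  s1 <- substr(paste0(fwd[2], JUNCTION_MOTIF, rev[4], "ACGT"), 1, 59)
  rp <- make_read_pairs(s1, seq2 = strrep("T", 59))  # mate 2 is garbage
  attr(rp, "trimmed") <- TRUE
  tab <- assign_primer_pairs(rp, p)
  expect_equal(attr(tab, "tallies")$assigned, 1L)
  expect_equal(tab$raw_count, 1L)
})

test_that("total-count normalization is exact and scale-invariant", {
  tab <- interaction_table(data.frame(fwd_id = c("F1", "F1", "F2"),
                                      rev_id = c("R1", "R2", "R1"),
                                      raw_count = c(2L, 3L, 5L)))
  n1 <- normalize_total(tab, 1)
  expect_equal(n1$norm_score, c(0.2, 0.3, 0.5))
  expect_equal(sum(n1$norm_score), 1)
  expect_error(normalize_total(tab, 0), "positive")

  tab2 <- interaction_table(data.frame(fwd_id = tab$fwd_id,
                                       rev_id = tab$rev_id,
                                       raw_count = tab$raw_count * 2L))
  expect_equal(normalize_total(tab2, 3.7)$norm_score,
               normalize_total(tab, 3.7)$norm_score)
})

test_that("binning aggregates by median and never zero-fills", {
  p <- structure(data.frame(
    id = c("F1", "R1", "R2"),
    chrom = "c", start = c(1000, 21000, 41000),
    end = c(1030, 21030, 41030),
    orientation = c("forward", "reverse", "reverse"),
    tail = c("T7", "T3", "T3"),
    sequence = c(strrep("A", 30), strrep("C", 30), strrep("G", 30))),
    class = c("primer_set", "data.frame"))
  # three pairs all landing in bin pair (0, 20000): scores 1, 9, 100
  tab <- interaction_table(data.frame(
    fwd_id = c("F1", "F1", "F1"), rev_id = c("R1", "R1", "R1"),
    raw_count = c(1L, 9L, 100L)))
  # pile the three scores into one cell by repeating the same pair
  cm <- bin_and_smooth(tab, p, chrom_length = 5e4, bin_size = 10000,
                       agg = function(x) stats::median(x))
  expect_equal(unname(cm$values["0", "20000"]), 9)      # median of 1,9,100
  expect_equal(unname(cm$values["20000", "0"]), 9)      # symmetry
  expect_true(is.na(cm$values["30000", "30000"]))       # empty bin absent
  expect_error(bin_and_smooth(tab, p, bin_size = 1e4, bin_step = 2e4),
               "bin_step")
})

test_that("median smoothing leaves a constant matrix unchanged", {
  n <- 8
  m <- matrix(3.5, n, n)
  cm <- contact_matrix("c", 1e4, 1e4, seq(0, by = 1e4, length.out = n),
                       m, "raw")
  # smooth via bin_and_smooth's internal path: rebuild from a table is
  # awkward, so check the smoother property on the matrix directly
  sm <- het5c:::smooth_matrix(cm$values, w = 1L, smooth_agg = stats::median)
  expect_equal(sm, m, ignore_attr = TRUE)
})

test_that("obs/exp transform: self-consistency and arithmetic", {
  # matrix generated exactly from its own distance profile -> all zeros
  n <- 10
  bs <- seq(0, by = 1e4, length.out = n)
  decay <- function(d) 100 / (1 + d / 1e4)
  m <- outer(bs, bs, function(a, b) decay(abs(a - b)))
  cm <- contact_matrix("c", 1e4, 1e4, bs, m, "raw")
  oe <- fit_expected_and_log2(cm)
  expect_true(all(abs(oe$matrix$values) < 1e-12))

  # one cell at 2x its stratum expected -> exactly 1.0
  m2 <- m
  m2[1, 3] <- m2[3, 1] <- 2 * decay(2e4)
  # stratum median must stay at the decay value, so bump only one of many
  cm2 <- contact_matrix("c", 1e4, 1e4, bs, m2, "raw")
  oe2 <- fit_expected_and_log2(cm2)
  expect_equal(unname(oe2$matrix$values[1, 3]), 1.0)
  expect_true(all(valid_interactions(oe2$matrix)[1, 3]))

  # planted TADs: valid fraction higher inside TADs than between
  g <- fixture_genome(seed = 31)
  p <- generate_primer_set(g)
  tab <- normalize_total(simulate_contact_counts(p, fixture_model(),
                                                 seed = 31)[[1]], 1)
  cm3 <- bin_and_smooth(tab, p, chrom_length = 1e6)
  oe3 <- fit_expected_and_log2(cm3)
  valid <- valid_interactions(oe3$matrix)
  tads <- default_tad_layout()
  mids <- oe3$matrix$bin_starts + 5e3
  tid <- het5c:::locate_in_tads("chr2L_het", mids, tads)
  same <- outer(tid, tid, function(a, b) !is.na(a) & !is.na(b) & a == b)
  diff <- outer(tid, tid, function(a, b) !is.na(a) & !is.na(b) & a != b)
  obs <- !is.na(oe3$matrix$values)
  expect_gt(sum(valid & same) / sum(obs & same),
            sum(valid & diff) / sum(obs & diff))
})

test_that("matrix TSV and pairwise-list IO round-trip", {
  g <- toy_genome(chrom_lengths = 2e5, seed = 41)
  p <- generate_primer_set(g, spacing = 10000)
  tab <- normalize_total(simulate_contact_counts(
    p, planted_tad_model(data.frame(chrom = "chr2L_het", start = 1e4,
                                    end = 1.5e5, activity = "active"),
                         read_depth = 5e3), seed = 41)[[1]], 2)
  cm <- bin_and_smooth(tab, p, chrom_length = 2e5)
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(cm, f)
  cm2 <- read_matrix_tsv(f)
  expect_equal(cm2$values, cm$values, ignore_attr = TRUE)
  expect_equal(cm2$bin_size, cm$bin_size)

  f2 <- tempfile(fileext = ".tsv")
  write_interaction_pairs(tab, p, f2)
  back <- read_interaction_pairs(f2)
  expect_equal(back$score, tab$norm_score)
  expect_equal(back$fwd_id, tab$fwd_id)
})
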