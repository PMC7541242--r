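test_that("primer tiling alternates forward/reverse at the set spacing", {
  g <- toy_genome(chrom_lengths = 6e5, seed = 11)
  p <- generate_primer_set(g, spacing = 10000)
  expect_equal(nrow(p), 60L)
  expect_equal(sum(p$orientation == "forward"), 30L)
  expect_equal(sum(p$orientation == "reverse"), 30L)
  # strictly alternating along the chromosome, forward first
  expect_equal(p$orientation[order(p$start)],
               rep(c("forward", "reverse"), 30L))
  # orientation <-> universal tail pairing
  expect_true(all(p$tail[p$orientation == "forward"] == "T7"))
  expect_true(all(p$tail[p$orientation == "reverse"] == "T3"))
  expect_false(anyDuplicated(p$sequence) > 0)
  expect_true(all(nchar(p$sequence) == 30L))
})

test_that("degenerate spacing and determinism behave as specified", {
  g <- toy_genome(chrom_lengths = 6e5, seed = 11)
  p1 <- generate_primer_set(g, spacing = 6e5)
  expect_lte(nrow(p1), 1L)
  expect_warning(p2 <- generate_primer_set(toy_genome(chrom_lengths = 5e3,
                                                      seed = 1),
                                           spacing = 1e4),
                 "no primers")
  expect_equal(nrow(p2), 0L)
  expect_identical(generate_primer_set(g, spacing = 2e4),
                   generate_primer_set(g, spacing = 2e4))
  expect_error(generate_primer_set(g, spacing = 500), ">= 1 kb")
})

test_that("contact simulation plants distance decay and TAD enrichment", {
  g <- fixture_genome(seed = 2)
  p <- generate_primer_set(g)
  m <- fixture_model(within_tad_factor = 5, between_tad_factor = 1)
  tabs <- simulate_contact_counts(p, m, seed = 2)
  expect_length(tabs, 3L)

  # brute-force mean comparison at matched distance, pooled over replicates
  pairs <- het5c:::enumerate_fr_pairs(p, m)
  counts <- matrix(0, nrow(pairs), 3L)
  key <- paste(pairs$fwd_id, pairs$rev_id)
  for (r in 1:3) {
    tk <- paste(tabs[[r]]$fwd_id, tabs[[r]]$rev_id)
    counts[match(tk, key), r] <- tabs[[r]]$raw_count
  }
  mean_count <- rowMeans(counts)
  dstrat <- round(pairs$distance / 5e4)
  shared <- Filter(function(s)
    sum(pairs$same_tad & dstrat == s) >= 10 &&
    sum(!pairs$same_tad & dstrat == s) >= 10,
    intersect(unique(dstrat[pairs$same_tad]),
              unique(dstrat[!pairs$same_tad])))
  for (s in shared) {
    expect_gt(mean(mean_count[pairs$same_tad & dstrat == s]),
              mean(mean_count[!pairs$same_tad & dstrat == s]))
  }
})

test_that("doubling read depth doubles totals within Poisson error", {
  g <- fixture_genome(seed = 3)
  p <- generate_primer_set(g)
  t1 <- simulate_contact_counts(p, fixture_model(read_depth = 1e5),
                                seed = 9)[[1]]
  t2 <- simulate_contact_counts(p, fixture_model(read_depth = 2e5),
                                seed = 9)[[1]]
  n1 <- sum(t1$raw_count)
  n2 <- sum(t2$raw_count)
  expect_lt(abs(n1 - 1e5), 3 * sqrt(1e5))
  expect_lt(abs(n2 - 2e5), 3 * sqrt(2e5))
})

test_that("simulation determinism, zero depth and flat-null behaviour", {
  g <- fixture_genome(seed = 4)
  p <- generate_primer_set(g)
  m <- fixture_model()
  expect_identical(simulate_contact_counts(p, m, seed = 5),
                   simulate_contact_counts(p, m, seed = 5))

  z <- simulate_contact_counts(p, fixture_model(read_depth = 0), seed = 1)
  expect_equal(nrow(z[[1]]), 0L)
  expect_true(attr(z[[1]], "zero_depth"))

  # flat factors: the fitted decay explains the matrix, mean log2 ~ 0
  null_m <- fixture_model(within_tad_factor = 1, between_tad_factor = 1)
  tab <- normalize_total(simulate_contact_counts(p, null_m, seed = 6)[[1]], 1)
  cm <- bin_and_smooth(tab, p, chrom_length = 1e6)
  oe <- fit_expected_and_log2(cm)
  v <- oe$matrix$values
  expect_lt(abs(mean(v[!is.na(v)])), 0.1)
})

test_that("feature tracks honour the fold-enrichment contract", {
  g <- fixture_genome(seed = 5)
  m <- fixture_model()
  truth <- synthetic_truth(m, feature_enrichment = c(flat = 1, mar = 10))
  # fold = 1: border-window density matches the genome-wide density
  hw <- 15000
  b <- truth$boundaries$position
  win_bp <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(pmax(0, b - hw) + 1, pmin(1e6, b + hw)))))
  rates <- replicate(10, {
    trk <- generate_feature_tracks(truth, g,
                                   seed = sample.int(1e6, 1))
    iv <- trk$flat$intervals
    mids <- (iv$start + iv$end) / 2
    in_win <- vapply(mids, function(x) any(abs(x - b) <= hw), logical(1))
    mean(in_win)
  })
  expect_lt(abs(mean(rates) - win_bp / 1e6),
            3 * stats::sd(rates) / sqrt(length(rates)) + 0.02)
  # fold = 10: per-bp interval density in windows dwarfs the outside
  trk <- generate_feature_tracks(truth, g, seed = 5)
  iv <- trk$mar$intervals
  mids <- (iv$start + iv$end) / 2
  in_win <- vapply(mids, function(x) any(abs(x - b) <= hw), logical(1))
  merged <- IRanges::reduce(IRanges::IRanges(pmax(0, b - hw) + 1,
                                             pmin(1e6, b + hw)))
  wbp <- sum(IRanges::width(merged))
  dens_in <- sum(in_win) / wbp
  dens_out <- sum(!in_win) / (1e6 - wbp)
  expect_gt(dens_in / dens_out, 5)
  expect_identical(generate_feature_tracks(truth, g, seed = 5),
                   generate_feature_tracks(truth, g, seed = 5))
})

test_that("expression generator: noise, straddlers, determinism", {
  g <- fixture_genome(seed = 6)
  truth <- synthetic_truth(fixture_model())
  e0 <- generate_expression_table(truth, g, seed = 3, rep_sdlog = 0)
  expect_equal(e0$fpkm_1, e0$fpkm_2)
  expect_equal(e0$fpkm_1, e0$fpkm_3)

  # straddle rate 0: every gene fully inside one TAD
  tads <- truth$model$tads
  contained <- mapply(function(ch, s, e) {
    any(tads$chrom == ch & tads$start <= s & tads$end >= e)
  }, e0$chrom, e0$start, e0$end)
  expect_true(all(contained))

  e1 <- generate_expression_table(truth, g, seed = 3, straddle_rate = 1)
  rec <- categorize_expression(e1, tads)
  expect_true(all(rec$straddle))

  expect_identical(generate_expression_table(truth, g, seed = 8),
                   generate_expression_table(truth, g, seed = 8))
})

test_that("emitted read pairs round-trip through the quantifier", {
  g <- toy_genome(chrom_lengths = 1e5, seed = 9)
  p <- generate_primer_set(g, spacing = 10000)
  fid <- p$id[p$orientation == "forward"]
  rid <- p$id[p$orientation == "reverse"]
  tab <- interaction_table(data.frame(fwd_id = fid[1], rev_id = rid[2],
                                      raw_count = 7L))
  fq1 <- tempfile(fileext = ".fq"); fq2 <- tempfile(fileext = ".fq")
  on.exit(unlink(c(fq1, fq2)))

  # count 7, no decoys -> exactly 7 pairs assignable to (F1, R2)
  emit_read_pairs(tab, p, fq1, fq2, seed = 2)
  q <- quantify_fivec(fq1, fq2, p)
  expect_equal(nrow(q), 1L)
  expect_equal(q$raw_count, 7L)
  expect_equal(q$fwd_id, fid[1])
  expect_equal(attr(q, "tallies")$assigned, 7L)

  # decoy fraction 1.0 -> nothing assignable
  emit_read_pairs(tab, p, fq1, fq2, seed = 2, decoy_fraction = 1)
  q0 <- quantify_fivec(fq1, fq2, p)
  expect_equal(nrow(q0), 0L)
  tl <- attr(q0, "tallies")
  expect_equal(tl$assigned, 0L)
  expect_equal(tl$ambiguous + tl$unmatched + tl$quality_dropped, 7L)

  # 30% of bases below Q25 in half the reads -> those fail the filter
  tab2 <- interaction_table(data.frame(fwd_id = fid[1], rev_id = rid[2],
                                       raw_count = 40L))
  emit_read_pairs(tab2, p, fq1, fq2, seed = 4,
                  low_quality_fraction = 0.5,
                  low_quality_base_fraction = 0.3)
  rp <- read_fastq_pairs(fq1, fq2)
  frac25 <- vapply(rp$qual1, function(qq) mean(utf8ToInt(qq) - 33 >= 25),
                   numeric(1))
  n_bad <- sum(frac25 < 0.8)
  expect_equal(n_bad, 20L)
  q2 <- quantify_fivec(fq1, fq2, p)
  expect_equal(attr(q2, "tallies")$quality_dropped, n_bad)
  expect_equal(q2$raw_count, 20L)
})
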