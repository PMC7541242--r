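test_that("DI reproduces the hand-evaluated formula", {
  # three bins, 10 kb window: centre bin sees A = 20 upstream, B = 60
  # downstream -> E = 40, DI = +(400/40 + 400/40) = +20
  bs <- c(0, 1e4, 2e4)
  m <- matrix(NA_real_, 3, 3)
  m[2, 1] <- m[1, 2] <- 20
  m[2, 3] <- m[3, 2] <- 60
  cm <- contact_matrix("c", 1e4, 1e4, bs, m, "raw")
  di <- compute_directionality_index(cm, window = 1e4)
  expect_equal(di$di[2], 20)
  expect_equal(di$E[2], 40)

  # A = B -> DI = 0 by the sign-term convention
  m[2, 3] <- m[3, 2] <- 20
  cm <- contact_matrix("c", 1e4, 1e4, bs, m, "raw")
  expect_equal(compute_directionality_index(cm, 1e4)$di[2], 0)

  # no data -> DI = 0, flagged
  m[] <- NA
  cm <- contact_matrix("c", 1e4, 1e4, bs, m, "raw")
  di <- compute_directionality_index(cm, 1e4)
  expect_true(all(di$di == 0))
  expect_true(all(di$no_data))
})

test_that("DI matches the naive double-loop oracle and antisymmetry", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(5:30, 1)
    cm <- random_contact_matrix(n)
    di <- compute_directionality_index(cm, window = 5e4)
    expect_equal(di$di, naive_di(cm$values, cm$bin_starts, 5e4))

    # reflecting the matrix negates and reverses the DI profile
    rev_vals <- cm$values[n:1, n:1]
    cm_rev <- contact_matrix("c", cm$bin_size, cm$bin_step,
                             cm$bin_starts, rev_vals, "raw")
    di_rev <- compute_directionality_index(cm_rev, window = 5e4)
    expect_equal(di_rev$di, -rev(di$di))
  }
})

test_that("HMM segments a noiseless biased profile correctly", {
  # +20 for 10 bins then -20 for 10 bins -> downstream then upstream runs
  prof <- structure(
    data.frame(bin_start = seq(0, by = 1e4, length.out = 20),
               A = 0, B = 0, E = 0,
               di = rep(c(20, -20), each = 10), no_data = FALSE),
    chrom = "c", bin_size = 1e4, window = 5e4,
    class = c("di_profile", "data.frame"))
  fit <- fit_bias_hmm(prof, seed = 1)
  expect_equal(as.character(fit$path),
               rep(c("downstream_bias", "upstream_bias"), each = 10))

  # DI identically zero -> everything no_bias, zero TADs downstream
  prof$di <- 0
  fit0 <- fit_bias_hmm(prof, seed = 1)
  expect_true(all(fit0$path == "no_bias"))
  ts <- extract_tads(fit0$path, prof$bin_start, 1e4, "c")
  expect_equal(nrow(ts$tads), 0L)

  # precondition: profile must span at least 2 windows
  expect_error(fit_bias_hmm(prof[1:5, ], seed = 1), "too short")
})

test_that("Viterbi decoding agrees with hand-set parameters", {
  A <- matrix(c(0.9, 0.05, 0.05,
                0.05, 0.9, 0.05,
                0.05, 0.05, 0.9), 3, byrow = TRUE)
  B <- matrix(c(0.8, 0.15, 0.05,
                0.2, 0.6, 0.2,
                0.05, 0.15, 0.8), 3, byrow = TRUE)
  obs <- c(1, 1, 1, 2, 3, 3, 3)
  path <- viterbi_path(obs, A, B)
  expect_equal(path, c(1, 1, 1, 1, 3, 3, 3))
})

test_that("TAD extraction follows the run rules", {
  bs <- seq(0, by = 1e4, length.out = 6)
  # D,D,D,N,U,U -> one TAD covering all six bins
  path <- c("downstream_bias", "downstream_bias", "downstream_bias",
            "no_bias", "upstream_bias", "upstream_bias")
  ts <- extract_tads(path, bs, 1e4, "c")
  expect_equal(nrow(ts$tads), 1L)
  expect_equal(ts$tads$start, 0)
  expect_equal(ts$tads$end, 6e4)

  # open downstream run with no closing upstream run is dropped and logged
  path2 <- c("no_bias", "no_bias", "downstream_bias", "downstream_bias",
             "no_bias", "no_bias")
  ts2 <- extract_tads(path2, bs, 1e4, "c")
  expect_equal(nrow(ts2$tads), 0L)
  expect_equal(attr(ts2, "n_open_dropped"), 1L)

  # runs shorter than min_run are absorbed into no_bias
  path3 <- c("downstream_bias", "no_bias", "no_bias", "no_bias",
             "upstream_bias", "no_bias")
  ts3 <- extract_tads(path3, bs, 1e4, "c", min_run = 2L)
  expect_equal(nrow(ts3$tads), 0L)

  # two adjacent domains leave a border gap between them
  bs8 <- seq(0, by = 1e4, length.out = 8)
  path4 <- c("downstream_bias", "downstream_bias", "upstream_bias",
             "upstream_bias", "downstream_bias", "downstream_bias",
             "upstream_bias", "upstream_bias")
  ts4 <- extract_tads(path4, bs8, 1e4, "c")
  expect_equal(nrow(ts4$tads), 2L)
  expect_equal(nrow(ts4$borders), 1L)
  expect_equal(ts4$borders$start, ts4$tads$end[1])
  expect_equal(ts4$borders$end, ts4$tads$start[2])
})

test_that("consensus clustering matches the stated examples", {
  mk <- function(pos, rep) tad_set_from_positions(pos, replicate = rep)
  # boundaries at 100/120/140 kb in three replicates -> consensus 120 kb
  sets <- list(mk(c(1e5, 4e5), 1), mk(c(1.2e5, 4e5), 2),
               mk(c(1.4e5, 4e5), 3))
  cons <- consensus_boundaries(sets, tolerance = 5e4, min_support = 2L)
  b <- attr(cons, "report")$boundaries
  expect_true(1.2e5 %in% b$position)

  # identical replicate sets: consensus boundaries equal any replicate's
  same <- list(mk(c(1e5, 2e5, 3e5, 4e5), 1), mk(c(1e5, 2e5, 3e5, 4e5), 2),
               mk(c(1e5, 2e5, 3e5, 4e5), 3))
  cons2 <- consensus_boundaries(same, tolerance = 5e4)
  expect_equal(sort(attr(cons2, "report")$boundaries$position),
               c(1e5, 2e5, 3e5, 4e5))
  expect_equal(attr(cons2, "report")$support_fraction, 1)
  expect_equal(cons2$tads[, c("chrom", "start", "end")],
               same[[1]]$tads[, c("chrom", "start", "end")])

  # a boundary seen in only 1 of 3 replicates is excluded at min_support 2
  sets3 <- list(mk(c(1e5, 4e5), 1), mk(c(1e5, 4e5), 2),
                mk(c(1e5, 2.5e5, 2.8e5, 4e5), 3))
  cons3 <- consensus_boundaries(sets3, tolerance = 5e4, min_support = 2L)
  expect_false(any(abs(attr(cons3, "report")$boundaries$position - 2.65e5)
                   < 1e4))

  expect_warning(consensus_boundaries(sets, tolerance = 5e3,
                                      bin_size = 1e4),
                 "rarely merge")
  expect_error(consensus_boundaries(sets[1]), ">= 2 replicates")
})

test_that("stronger planted TADs never weaken border DI", {
  g <- fixture_genome(seed = 51)
  p <- generate_primer_set(g)
  truth <- synthetic_truth(fixture_model())
  border_bins <- unique(floor(truth$boundaries$position / 1e4) * 1e4)
  med_di <- vapply(c(2, 5, 10), function(f) {
    m <- fixture_model(within_tad_factor = f)
    tab <- normalize_total(simulate_contact_counts(p, m, seed = 51)[[1]], 1)
    cm <- bin_and_smooth(tab, p, chrom_length = 1e6)
    di <- compute_directionality_index(cm)
    stats::median(abs(di$di[di$bin_start %in% border_bins]))
  }, numeric(1))
  expect_true(all(diff(med_di) >= 0))
})
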