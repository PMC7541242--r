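#' Interval set with a randomization universe
#'
#' A named collection of genomic intervals (0-based half-open) together
#' with the per-chromosome span permutations are allowed to draw from. For
#' targeted 5C designs the universe is the designed region set, not the
#' whole genome — randomizing pericentromeric queries genome-wide would
#' inflate Z-scores trivially.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param universe data.frame with `chrom`, `start`, `end` giving the
#'   allowed span per chromosome, or a [toy_genome()].
#' @param name label for reporting.
#' @return object of class `interval_set`.
#' @export
interval_set <- function(intervals, universe, name = "") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (inherits(universe, "toy_genome"))
    universe <- data.frame(chrom = universe$chrom_names, start = 0,
                           end = unname(universe$chrom_lengths))
  stopifnot(is.data.frame(universe),
            all(c("chrom", "start", "end") %in% names(universe)))
  if (nrow(intervals) > 0L) {
    if (any(intervals$end <= intervals$start))
      stop("intervals must have end > start")
    u <- universe[match(intervals$chrom, universe$chrom), ]
    if (anyNA(u$chrom) || any(intervals$start < u$start) ||
        any(intervals$end > u$end))
      stop("intervals must lie within the universe")
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, intervals = intervals, universe = universe),
            class = "interval_set")
}

# 0-based half-open data.frame -> GRanges (1-based closed).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

coerce_intervals <- function(x) {
  if (inherits(x, "interval_set")) x$intervals else x
}

#' Count query intervals overlapping a feature set
#'
#' Half-open overlap of >= 1 bp; the unit is query intervals overlapped,
#' not base pairs, and merging overlapping feature intervals does not
#' change the count.
#'
#' @param query,feature `interval_set`s or plain interval data.frames.
#' @return integer count.
#' @export
count_overlaps <- function(query, feature) {
  q <- coerce_intervals(query)
  f <- coerce_intervals(feature)
  if (nrow(q) == 0L || nrow(f) == 0L) return(0L)
  sum(GenomicRanges::countOverlaps(as_granges0(q), as_granges0(f)) > 0L)
}

#' Permutation test for interval-overlap enrichment
#'
#' Each permutation redraws the query intervals uniformly within the
#' declared universe, preserving per-interval lengths and chromosome
#' assignment, and recounts the overlap. The p-value uses the add-one
#' estimator p = (1 + #\{perm >= obs\}) / (1 + n_permutations) (for
#' `alternative = "greater"`), so it is never exactly 0; the Z-score is
#' (observed - mean) / sd of the permutation null and is reported as `NA`
#' when the null has zero spread.
#'
#' @param query an [interval_set()] (its universe drives randomization).
#' @param feature an `interval_set` or interval data.frame.
#' @param n_permutations number of permutations (default 1000).
#' @param alternative `"greater"` (enrichment) or `"less"` (depletion).
#' @param seed integer seed; identical seed gives identical results.
#' @return object of class `perm_test` with fields `observed_overlap`,
#'   `n_permutations`, `perm_mean`, `perm_sd`, `z_score`, `p_value`,
#'   `alternative`, `seed`.
#' @export
permutation_overlap_test <- function(query, feature, n_permutations = 1000L,
                                     alternative = c("greater", "less"),
                                     seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(query, "interval_set"))
  f <- coerce_intervals(feature)
  q <- query$intervals
  if (nrow(q) == 0L || nrow(f) == 0L)
    stop("query and feature must be non-empty")
  observed <- count_overlaps(q, f)

  set.seed(derive_seed(seed, 11L))
  widths <- q$end - q$start
  u <- query$universe[match(q$chrom, query$universe$chrom), ]
  lo <- u$start
  hi <- u$end - widths
  if (any(hi < lo)) stop("universe too small for an interval width")

  nq <- nrow(q)
  starts <- floor(matrix(stats::runif(nq * n_permutations,
                                      min = rep(lo, n_permutations),
                                      max = rep(hi + 1, n_permutations)),
                         nrow = nq))
  starts <- pmin(starts, rep(hi, n_permutations))  # guard the open edge
  perm_gr <- GenomicRanges::GRanges(
    rep(q$chrom, n_permutations),
    IRanges::IRanges(start = as.vector(starts) + 1,
                     width = rep(widths, n_permutations)))
  fgr <- GenomicRanges::reduce(as_granges0(f))
  hit <- GenomicRanges::countOverlaps(perm_gr, fgr) > 0L
  perm_counts <- as.vector(rowsum(as.integer(hit),
                                  rep(seq_len(n_permutations), each = nq)))

  perm_mean <- mean(perm_counts)
  perm_sd <- stats::sd(perm_counts)
  extreme <- if (alternative == "greater") perm_counts >= observed
             else perm_counts <= observed
  p <- (1 + sum(extreme)) / (1 + n_permutations)
  z <- if (perm_sd > 0) (observed - perm_mean) / perm_sd else NA_real_
  structure(list(observed_overlap = observed,
                 n_permutations = n_permutations,
                 perm_mean = perm_mean, perm_sd = perm_sd,
                 z_score = z, p_value = p,
                 alternative = alternative, seed = seed,
                 feature = if (inherits(feature, "interval_set"))
                   feature$name else ""),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> %s obs=%d null=%.2f+/-%.2f Z=%s p=%.4g (%s, %d perms)\n",
    x$feature, x$observed_overlap, x$perm_mean, x$perm_sd,
    ifelse(is.na(x$z_score), "NA", sprintf("%.2f", x$z_score)),
    x$p_value, x$alternative, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg adjustment over a list of permutation tests
#'
#' Raw permutation p-values are what 5C border-enrichment analyses report;
#' adjustment across features is opt-in via this helper.
#'
#' @param tests list of `perm_test` objects.
#' @return data.frame with feature, observed, z, raw and BH-adjusted p.
#' @export
adjust_perm_tests <- function(tests) {
  df <- data.frame(
    feature = vapply(tests, function(t) t$feature, character(1)),
    observed = vapply(tests, function(t) t$observed_overlap, numeric(1)),
    z_score = vapply(tests, function(t) t$z_score, numeric(1)),
    p_value = vapply(tests, function(t) t$p_value, numeric(1)))
  df$p_adjusted <- stats::p.adjust(df$p_value, method = "BH")
  df
}

#' Scaled meta-region feature profile
#'
#' Rescales each region to the canonical length of its class — TAD borders
#' to 30 kb in 10 kb bins (3 bins), intra-TAD regions to 150 kb in 30 kb
#' bins (5 bins) — and averages, per canonical bin, the number of feature
#' intervals overlapping the corresponding fraction of each real region.
#'
#' @param regions interval data.frame or `interval_set` (e.g. borders or
#'   TAD bodies).
#' @param feature `interval_set` or interval data.frame.
#' @param region_class `"border"` or `"intra_tad"` (sets the bin count).
#' @param n_bins override the canonical bin count.
#' @return object of class `scaled_profile` with per-bin mean overlap
#'   counts.
#' @export
scaled_profile <- function(regions, feature,
                           region_class = c("border", "intra_tad"),
                           n_bins = NULL) {
  region_class <- match.arg(region_class)
  r <- coerce_intervals(regions)
  f <- coerce_intervals(feature)
  if (nrow(r) == 0L) stop("no regions to profile")
  if (is.null(n_bins))
    n_bins <- if (region_class == "border") 3L else 5L

  counts <- matrix(0, nrow(r), n_bins)
  fgr <- as_granges0(f)
  for (i in seq_len(nrow(r))) {
    edges <- r$start[i] + (r$end[i] - r$start[i]) * (0:n_bins) / n_bins
    sub <- data.frame(chrom = r$chrom[i],
                      start = edges[-(n_bins + 1L)], end = edges[-1L])
    counts[i, ] <- GenomicRanges::countOverlaps(as_granges0(sub), fgr)
  }
  structure(list(feature = if (inherits(feature, "interval_set"))
                   feature$name else "",
                 region_class = region_class,
                 n_bins = n_bins,
                 values = colMeans(counts),
                 n_regions = nrow(r)),
            class = "scaled_profile")
}

#' Feature-combination counts over interaction anchors
#'
#' Labels each anchor interval with the exact subset of features it
#' overlaps and counts anchors per subset — the count table behind an
#' UpSet-style view of inter-chromosomal anchor annotation.
#'
#' @param anchors interval data.frame or `interval_set` (e.g. 10 kb-binned
#'   inter-chromosomal interaction endpoints).
#' @param features named list of `interval_set`s / interval data.frames.
#' @return data.frame with `combination` ("A+B", "none", ...) and `count`;
#'   counts sum to the number of anchors.
#' @export
anchor_feature_combinations <- function(anchors, features) {
  a <- coerce_intervals(anchors)
  stopifnot(length(names(features)) == length(features))
  agr <- as_granges0(a)
  lab <- matrix(FALSE, nrow(a), length(features),
                dimnames = list(NULL, names(features)))
  for (nm in names(features)) {
    f <- coerce_intervals(features[[nm]])
    if (nrow(f))
      lab[, nm] <- GenomicRanges::countOverlaps(agr, as_granges0(f)) > 0L
  }
  key <- apply(lab, 1L, function(row) {
    nm <- colnames(lab)[row]
    if (length(nm) == 0L) "none" else paste(nm, collapse = "+")
  })
  out <- as.data.frame(table(combination = key),
                       responseName = "count",
                       stringsAsFactors = FALSE)
  attr(out, "n_anchors") <- nrow(a)
  out
}
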