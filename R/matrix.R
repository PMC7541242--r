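#' Binned contact matrix
#'
#' Symmetric per-chromosome matrix of binned interaction scores. Absent
#' cells are `NA`, never zero-filled: a missing observation is not an
#' observed zero.
#'
#' @param chrom chromosome name.
#' @param bin_size,bin_step bin window and step in bp (`bin_step <=
#'   bin_size`; equal means non-overlapping bins).
#' @param bin_starts sorted bin start coordinates (0-based).
#' @param values square numeric matrix, `NA` = absent; must be symmetric.
#' @param kind `"raw"` or `"obs_exp_log2"`; for the latter an entry is a
#'   "valid" interaction iff its value is strictly positive.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, bin_step, bin_starts, values,
                           kind = c("raw", "obs_exp_log2")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            nrow(values) == length(bin_starts))
  if (bin_step > bin_size) stop("bin_step must not exceed bin_size")
  sym <- values == t(values)
  if (!all(sym | (is.na(values) & is.na(t(values)))))
    stop("contact matrix must be symmetric")
  dimnames(values) <- list(bin_starts, bin_starts)
  structure(list(chrom = chrom, bin_size = bin_size, bin_step = bin_step,
                 bin_starts = bin_starts, values = values, kind = kind),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %g bp (step %g), kind=%s, %d cells observed\n",
              x$chrom, length(x$bin_starts), x$bin_size, x$bin_step,
              x$kind, sum(!is.na(x$values))))
  invisible(x)
}

#' Bin primer-pair scores into a contact matrix, with optional smoothing
#'
#' Each cell (i, j) aggregates (default: median) the scores of primer pairs
#' whose anchor midpoints fall in bin windows i and j. With `bin_step <
#' bin_size` the bins overlap (sliding windows). Smoothing then replaces
#' each observed cell by the `smooth_agg` of observed cells within
#' `smooth_span` bp on both axes; absent cells stay absent.
#'
#' @param table an [interaction_table()] (normalized scores are used when
#'   present, raw counts otherwise).
#' @param primers the `primer_set`, used for anchor coordinates.
#' @param chrom chromosome to bin (default: the only chromosome present).
#' @param chrom_length length in bp (default: rightmost primer end).
#' @param bin_size,bin_step binning parameters in bp (defaults 10 kb /
#'   10 kb; a 1 kb step reproduces sliding-window heatmaps).
#' @param agg,smooth_agg aggregation functions (default median).
#' @param smooth_span +/- span of the smoother in bp; 0 disables.
#' @return a [contact_matrix()] of kind `"raw"`.
#' @export
bin_and_smooth <- function(table, primers, chrom = NULL, chrom_length = NULL,
                           bin_size = 10000, bin_step = bin_size,
                           agg = stats::median,
                           smooth_span = 0, smooth_agg = stats::median) {
  stopifnot(is.data.frame(table))
  validate_primer_set(primers)
  if (bin_step > bin_size) stop("bin_step must not exceed bin_size")
  pinfo <- primers[match(c(table$fwd_id, table$rev_id), primers$id), ]
  if (anyNA(pinfo$id)) stop("table refers to primers absent from the catalog")
  npair <- nrow(table)
  ch1 <- pinfo$chrom[seq_len(npair)]
  ch2 <- pinfo$chrom[npair + seq_len(npair)]
  if (is.null(chrom)) {
    chrom <- unique(c(ch1, ch2))
    if (length(chrom) > 1L)
      stop("multiple chromosomes present; pass `chrom` explicitly")
  }
  on_ch <- ch1 == chrom & ch2 == chrom
  mid1 <- ((pinfo$start + pinfo$end) / 2)[seq_len(npair)][on_ch]
  mid2 <- ((pinfo$start + pinfo$end) / 2)[npair + seq_len(npair)][on_ch]
  scores <- interaction_scores(table)[on_ch]
  if (is.null(chrom_length))
    chrom_length <- max(primers$end[primers$chrom == chrom])
  bin_starts <- seq(0, max(0, chrom_length - 1), by = bin_step)
  nb <- length(bin_starts)

  # bins whose window [s, s + bin_size) contains a midpoint
  bins_of <- function(mid) {
    lo <- findInterval(mid - bin_size, bin_starts, left.open = TRUE) + 1L
    hi <- findInterval(mid, bin_starts)
    Map(seq.int, pmin(lo, hi), hi)
  }
  b1 <- bins_of(mid1)
  b2 <- bins_of(mid2)
  reps <- lengths(b1) * lengths(b2)
  cell_i <- unlist(Map(function(a, b) rep(a, each = length(b)), b1, b2))
  cell_j <- unlist(Map(function(a, b) rep(b, times = length(a)), b1, b2))
  cell_s <- rep(scores, reps)

  values <- matrix(NA_real_, nb, nb)
  if (length(cell_s)) {
    key <- paste(pmin(cell_i, cell_j), pmax(cell_i, cell_j))
    aggd <- tapply(cell_s, key, agg)
    ij <- do.call(rbind, strsplit(names(aggd), " ", fixed = TRUE))
    i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
    values[cbind(i, j)] <- as.numeric(aggd)
    values[cbind(j, i)] <- as.numeric(aggd)
  }

  if (smooth_span > 0)
    values <- smooth_matrix(values, floor(smooth_span / bin_step),
                            smooth_agg)

  contact_matrix(chrom, bin_size, bin_step, bin_starts, values, "raw")
}

# Neighbourhood smoother: each observed cell becomes the aggregate of
# observed cells within +/- w bins on both axes; absent cells stay absent.
smooth_matrix <- function(values, w, smooth_agg = stats::median) {
  nb <- nrow(values)
  obs <- which(!is.na(values), arr.ind = TRUE)
  sm <- values
  for (r in seq_len(nrow(obs))) {
    i <- obs[r, 1L]; j <- obs[r, 2L]
    block <- values[max(1L, i - w):min(nb, i + w),
                    max(1L, j - w):min(nb, j + w)]
    sm[i, j] <- smooth_agg(block[!is.na(block)])
  }
  sm
}

#' Distance-decay expected model and log2 observed/expected transform
#'
#' The expected score at a given genomic separation is the median of all
#' observed scores in that distance stratum (stratum width = one bin). The
#' returned matrix holds `log2(observed / expected)`; entries with value
#' strictly greater than 0 are interactions enriched above the distance
#' baseline and hence "valid". Absent cells remain absent.
#'
#' @param cm a [contact_matrix()] of kind `"raw"`.
#' @param stat aggregation over a distance stratum (default median).
#' @return list with `matrix` (kind `"obs_exp_log2"`) and `expected`, an
#'   `expected_model` (distance-bin edges and the expected score each).
#' @export
fit_expected_and_log2 <- function(cm, stat = stats::median) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$kind != "raw") stop("expected model requires a raw-score matrix")
  nb <- length(cm$bin_starts)
  dmat <- abs(outer(cm$bin_starts, cm$bin_starts, "-"))
  stratum <- floor(dmat / cm$bin_size)
  obs <- !is.na(cm$values)
  strata <- sort(unique(stratum[obs]))
  expected <- vapply(strata, function(s)
    stat(cm$values[obs & stratum == s]), numeric(1))
  names(expected) <- strata
  emap <- expected[as.character(stratum)]
  emap[emap <= 0 | is.na(emap)] <- NA_real_
  ratio <- matrix(log2(cm$values / emap), nb, nb)
  model <- structure(
    list(distance_edges = c(strata, max(strata) + 1L) * cm$bin_size,
         expected = expected,
         bin_size = cm$bin_size, stat = "median"),
    class = "expected_model")
  list(matrix = contact_matrix(cm$chrom, cm$bin_size, cm$bin_step,
                               cm$bin_starts, ratio, "obs_exp_log2"),
       expected = model)
}

#' Valid-interaction mask of a log2 obs/exp matrix
#'
#' @param cm a `contact_matrix` of kind `"obs_exp_log2"`.
#' @return logical matrix: `TRUE` where the entry is present and > 0.
#' @export
valid_interactions <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"), cm$kind == "obs_exp_log2")
  !is.na(cm$values) & cm$values > 0
}
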