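#' Generate feature tracks with tunable border enrichment
#'
#' For each named feature, places background intervals uniformly over the
#' genome, then adds extra intervals within +/- `border_halfwidth` of the
#' planted TAD boundaries so that the expected interval density in border
#' windows is `fold` times the background density. `fold = 1` places no
#' extra intervals, giving a uniform track.
#'
#' @param truth a [synthetic_truth()] (supplies boundaries and per-feature
#'   folds).
#' @param genome the [toy_genome()].
#' @param seed integer seed.
#' @param background_per_mb background intervals per Mb (default 40).
#' @param interval_length feature interval length in bp (default 1 kb).
#' @param border_halfwidth half-width of the enriched window around each
#'   boundary (default 15 kb, matching a 30 kb scaled border).
#' @return named list of [interval_set()]s over the genome universe.
#' @export
generate_feature_tracks <- function(truth, genome, seed = 1L,
                                    background_per_mb = 40,
                                    interval_length = 1000,
                                    border_halfwidth = 15000) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(genome, "toy_genome"))
  if (length(genome$chrom_names) == 0L) stop("empty genome")
  folds <- truth$feature_enrichment
  out <- stats::setNames(vector("list", length(folds)), names(folds))
  for (fi in seq_along(folds)) {
    set.seed(derive_seed(seed, 200L + fi))
    fold <- folds[[fi]]
    ivs <- list()
    for (ch in genome$chrom_names) {
      len <- genome$chrom_lengths[[ch]]
      if (len <= interval_length) stop("chromosome shorter than interval")
      n_bg <- round(background_per_mb * len / 1e6)
      starts <- floor(stats::runif(n_bg, 0, len - interval_length))
      b <- truth$boundaries$position[truth$boundaries$chrom == ch]
      win_lo <- pmax(0, b - border_halfwidth)
      win_hi <- pmin(len - interval_length, b + border_halfwidth)
      win_w <- pmax(0, win_hi - win_lo)
      extra <- 0L
      if (fold > 1 && sum(win_w) > 0) {
        bg_in_windows <- n_bg * sum(win_w) / len
        extra <- round((fold - 1) * bg_in_windows)
      }
      if (extra > 0L) {
        wsel <- sample.int(length(win_w), extra, replace = TRUE,
                           prob = win_w / sum(win_w))
        estarts <- floor(win_lo[wsel] + stats::runif(extra) * win_w[wsel])
        starts <- c(starts, estarts)
      }
      ivs[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = starts + interval_length)
    }
    out[[fi]] <- interval_set(do.call(rbind, ivs), genome,
                              name = names(folds)[fi])
  }
  out
}

#' Generate a synthetic gene expression (FPKM) table
#'
#' Genes are tiled inside the planted TADs every `gene_spacing` bp. Each
#' gene draws a mean FPKM log-normally around its TAD's activity level
#' (active mean >> inactive mean); replicate FPKM values add log-normal
#' noise around the gene mean (mean-preserving). `category_noise` swaps a
#' fraction of genes to the opposite activity's distribution, and
#' `straddle_rate` moves a fraction of genes to span their TAD's end
#' boundary.
#'
#' @param truth a [synthetic_truth()].
#' @param genome the [toy_genome()].
#' @param n_replicates FPKM replicate columns (default 3).
#' @param seed integer seed.
#' @param gene_spacing,gene_length gene tiling parameters in bp.
#' @param gene_sdlog log-sd of gene means within a TAD activity class.
#' @param rep_sdlog replicate log-noise; 0 makes replicates identical.
#' @param straddle_rate probability a gene straddles its TAD end boundary.
#' @param category_noise probability a gene draws from the other activity
#'   class.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `fpkm_1..n`, and ground-truth columns `true_tad`, `true_mean`,
#'   `true_category`.
#' @export
generate_expression_table <- function(truth, genome, n_replicates = 3L,
                                      seed = 1L,
                                      gene_spacing = 20000,
                                      gene_length = 5000,
                                      gene_sdlog = 0.4,
                                      rep_sdlog = 0.15,
                                      straddle_rate = 0,
                                      category_noise = 0) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(genome, "toy_genome"))
  set.seed(derive_seed(seed, 400L))
  tads <- truth$model$tads
  rows <- list()
  gid <- 0L
  for (k in seq_len(nrow(tads))) {
    starts <- seq(tads$start[k],
                  max(tads$start[k], tads$end[k] - gene_length),
                  by = gene_spacing)
    starts <- starts[starts + gene_length <= tads$end[k]]
    for (s in starts) {
      gid <- gid + 1L
      active <- tads$activity[k] == "active"
      if (category_noise > 0 && stats::runif(1) < category_noise)
        active <- !active
      mu <- if (active) truth$active_mean_fpkm else truth$inactive_mean_fpkm
      gene_mean <- stats::rlnorm(1, meanlog = log(mu), sdlog = gene_sdlog)
      g_start <- s
      g_end <- s + gene_length
      if (straddle_rate > 0 && stats::runif(1) < straddle_rate) {
        g_start <- tads$end[k] - gene_length / 2
        g_end <- g_start + gene_length
      }
      fpkm <- gene_mean *
        stats::rlnorm(n_replicates, meanlog = -rep_sdlog^2 / 2,
                      sdlog = rep_sdlog)
      row <- data.frame(gene_id = sprintf("gene_%04d", gid),
                        chrom = tads$chrom[k],
                        start = g_start, end = g_end,
                        stringsAsFactors = FALSE)
      for (r in seq_len(n_replicates))
        row[[sprintf("fpkm_%d", r)]] <- fpkm[r]
      row$true_tad <- k
      row$true_mean <- gene_mean
      row$true_category <- as.character(categorize_fpkm(gene_mean))
      rows[[gid]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
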