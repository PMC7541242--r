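#' Simulate 5C contact counts with planted TAD structure
#'
#' Expected counts for a forward x reverse primer pair follow a power-law
#' distance decay, multiplied by `within_tad_factor` when both anchor
#' midpoints fall inside one planted TAD and by `between_tad_factor`
#' otherwise. The expectation is scaled so each replicate totals
#' `read_depth` pairs on average; replicate counts are then drawn Poisson
#' (or negative binomial when `nb_dispersion` is finite). Only forward x
#' reverse pairs on the same chromosome are populated, mirroring 5C
#' chemistry, which detects only F-R ligation junctions.
#'
#' @param primers a `primer_set` from [generate_primer_set()].
#' @param model a [planted_tad_model()].
#' @param seed integer seed; identical seed gives identical tables.
#' @param decay_floor distance floor in bp (default one 10 kb bin) that
#'   caps the decay at adjacent primers.
#' @return list of [interaction_table()]s, one per replicate. Zero
#'   `read_depth` yields all-zero tables flagged via the `zero_depth`
#'   attribute.
#' @export
simulate_contact_counts <- function(primers, model, seed = 1L,
                                    decay_floor = 10000) {
  validate_primer_set(primers)
  stopifnot(inherits(model, "planted_tad_model"))
  if (nrow(primers) < 2L) stop("need at least 2 primers")

  pairs <- enumerate_fr_pairs(primers, model)
  if (nrow(pairs) == 0L) stop("no forward x reverse pairs on any chromosome")

  d_eff <- pmax(pairs$distance, decay_floor)
  lambda <- (d_eff / decay_floor)^(-model$decay_exponent) *
    ifelse(pairs$same_tad, model$within_tad_factor, model$between_tad_factor)
  zero_depth <- model$read_depth <= 0
  scale <- if (zero_depth) 0 else model$read_depth / sum(lambda)
  lambda <- lambda * scale

  lapply(seq_len(model$n_replicates), function(r) {
    set.seed(derive_seed(seed, 100L + r))
    counts <- if (is.finite(model$nb_dispersion))
      stats::rnbinom(length(lambda), mu = lambda, size = model$nb_dispersion)
    else
      stats::rpois(length(lambda), lambda)
    keep <- counts > 0L
    tab <- interaction_table(
      data.frame(fwd_id = pairs$fwd_id[keep],
                 rev_id = pairs$rev_id[keep],
                 raw_count = counts[keep],
                 stringsAsFactors = FALSE),
      replicate = r)
    attr(tab, "zero_depth") <- zero_depth
    tab
  })
}

# All forward x reverse primer pairs on the same chromosome, with midpoint
# distance and same-TAD membership.
enumerate_fr_pairs <- function(primers, model = NULL) {
  out <- list()
  for (ch in unique(primers$chrom)) {
    p <- primers[primers$chrom == ch, ]
    fwd <- p[p$orientation == "forward", ]
    rev <- p[p$orientation == "reverse", ]
    if (nrow(fwd) == 0L || nrow(rev) == 0L) next
    g <- expand.grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
    mid_f <- (fwd$start + fwd$end) / 2
    mid_r <- (rev$start + rev$end) / 2
    df <- data.frame(
      fwd_id = fwd$id[g$fi], rev_id = rev$id[g$ri],
      chrom = ch,
      mid1 = mid_f[g$fi], mid2 = mid_r[g$ri],
      stringsAsFactors = FALSE)
    df$distance <- abs(df$mid1 - df$mid2)
    if (!is.null(model)) {
      t1 <- locate_in_tads(ch, df$mid1, model$tads)
      t2 <- locate_in_tads(ch, df$mid2, model$tads)
      df$same_tad <- !is.na(t1) & !is.na(t2) & t1 == t2
    }
    out[[ch]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Index of the TAD containing each position (NA when in a border gap or
# outside all TADs). Intervals are 0-based half-open.
locate_in_tads <- function(chrom, pos, tads) {
  idx <- rep(NA_integer_, length(pos))
  tc <- which(tads$chrom == chrom)
  for (k in tc) {
    inside <- pos >= tads$start[k] & pos < tads$end[k]
    idx[inside] <- k
  }
  idx
}
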