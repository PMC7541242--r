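#' Toy genome specification
#'
#' Describes the coordinate space the synthetic generators work in: a small
#' set of named chromosomes (stand-ins for pericentromeric regions) with
#' lengths in base pairs, plus a master seed that makes every downstream
#' generator reproducible.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp, one per
#'   chromosome, all positive.
#' @param seed integer master random seed.
#' @return An object of class `toy_genome`.
#' @export
toy_genome <- function(chrom_names = "chr2L_het",
                       chrom_lengths = 1e6L,
                       seed = 1L) {
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (length(chrom_names) == 0L)
    stop("toy genome must have at least one chromosome")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                         chrom_names),
         seed = as.integer(seed)),
    class = "toy_genome")
}

#' Planted TAD model
#'
#' Declares the ground-truth domain structure a synthetic 5C experiment is
#' simulated from: non-overlapping TAD intervals (each active or inactive),
#' a power-law distance decay for contact frequency, multiplicative contact
#' factors inside/between TADs, sequencing depth and replicate count.
#'
#' @param tads data.frame with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open) and `activity` ("active"/"inactive"). Must be sorted and
#'   non-overlapping per chromosome.
#' @param decay_exponent non-negative power-law slope of contact frequency
#'   versus genomic distance.
#' @param within_tad_factor multiplicative contact enrichment when both
#'   anchors fall inside one planted TAD.
#' @param between_tad_factor multiplicative factor for all other pairs;
#'   must satisfy `within_tad_factor > between_tad_factor > 0`.
#' @param read_depth expected total read-pair count per replicate.
#' @param n_replicates number of replicates to simulate (>= 1).
#' @param nb_dispersion optional negative-binomial size parameter; `Inf`
#'   (default) keeps counts pure Poisson.
#' @return An object of class `planted_tad_model`.
#' @export
planted_tad_model <- function(tads,
                              decay_exponent = 1,
                              within_tad_factor = 5,
                              between_tad_factor = 1,
                              read_depth = 2e5,
                              n_replicates = 3L,
                              nb_dispersion = Inf) {
  stopifnot(is.data.frame(tads),
            all(c("chrom", "start", "end", "activity") %in% names(tads)))
  # equality of the two factors is the structureless null model
  if (!(within_tad_factor >= between_tad_factor && between_tad_factor > 0))
    stop("need within_tad_factor >= between_tad_factor > 0")
  if (decay_exponent < 0) stop("decay_exponent must be >= 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  tads <- tads[order(tads$chrom, tads$start), , drop = FALSE]
  for (ch in unique(tads$chrom)) {
    tc <- tads[tads$chrom == ch, ]
    if (any(tc$end <= tc$start)) stop("TAD intervals must have end > start")
    if (nrow(tc) > 1L && any(tc$start[-1L] < tc$end[-nrow(tc)]))
      stop("planted TADs overlap on ", ch)
  }
  structure(
    list(tads = tads,
         decay_exponent = decay_exponent,
         within_tad_factor = within_tad_factor,
         between_tad_factor = between_tad_factor,
         read_depth = read_depth,
         n_replicates = as.integer(n_replicates),
         nb_dispersion = nb_dispersion),
    class = "planted_tad_model")
}

#' Default planted-TAD layout for a 1 Mb toy chromosome
#'
#' Six domains of 100-250 kb separated by 10-20 kb border gaps, alternating
#' active/inactive, matching the scale of pericentromeric Het TADs
#' (90 kb - 0.3 Mb) while staying small enough for fast tests.
#'
#' @param chrom chromosome name the layout is placed on.
#' @return data.frame suitable for the `tads` argument of
#'   [planted_tad_model()].
#' @export
default_tad_layout <- function(chrom = "chr2L_het") {
  starts <- c(10000, 180000, 330000, 560000, 680000, 840000)
  ends   <- c(160000, 310000, 540000, 670000, 820000, 990000)
  data.frame(
    chrom = chrom,
    start = starts,
    end = ends,
    activity = rep(c("active", "inactive"), 3L),
    stringsAsFactors = FALSE)
}

#' Ground truth bundle for a synthetic experiment
#'
#' Collects the planted boundaries (sorted TAD edges), per-feature border
#' fold-enrichments and per-TAD expression draw parameters so downstream
#' checks can compare pipeline output with what was planted.
#'
#' @param model a [planted_tad_model()].
#' @param feature_enrichment named numeric vector, feature name ->
#'   fold-enrichment (>= 1) at planted borders.
#' @param active_mean_fpkm,inactive_mean_fpkm mean FPKM of genes in active /
#'   inactive TADs (log-normal location on the natural scale).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(model,
                            feature_enrichment = c(MAR = 10, BEAF32 = 5),
                            active_mean_fpkm = 50,
                            inactive_mean_fpkm = 0.3) {
  if (any(feature_enrichment < 1))
    stop("fold-enrichments must be >= 1")
  tads <- model$tads
  b <- data.frame(chrom = rep(tads$chrom, 2L),
                  position = c(tads$start, tads$end))
  b <- b[order(b$chrom, b$position), , drop = FALSE]
  b <- unique(b)
  rownames(b) <- NULL
  structure(
    list(model = model,
         boundaries = b,
         feature_enrichment = feature_enrichment,
         active_mean_fpkm = active_mean_fpkm,
         inactive_mean_fpkm = inactive_mean_fpkm),
    class = "synthetic_truth")
}

# Derive a stream-specific 32-bit seed from a master seed so that
# independent generators never share a random stream.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 97) %%
               2147483647)
}
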