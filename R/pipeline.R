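#' het5c: pericentromeric 5C analysis with planted-truth validation
#'
#' Pipeline stages: synthetic-data generation with planted TADs
#' ([generate_primer_set()], [simulate_contact_counts()],
#' [emit_read_pairs()], [generate_feature_tracks()],
#' [generate_expression_table()]); 5C quantification
#' ([quantify_fivec()], [bin_and_smooth()], [fit_expected_and_log2()]);
#' TAD calling ([compute_directionality_index()], [fit_bias_hmm()],
#' [extract_tads()], [consensus_boundaries()]); border feature statistics
#' ([permutation_overlap_test()], [scaled_profile()],
#' [anchor_feature_combinations()]); and condition comparison /
#' expression integration ([classify_interactions()],
#' [summarize_distributions()], [categorize_expression()],
#' [tad_expression_concordance()]).
#'
#' @keywords internal
#' @aliases het5c-package
"_PACKAGE"

#' Call TADs from a binned contact matrix
#'
#' Convenience wrapper chaining Directionality Index computation, HMM
#' segmentation and TAD extraction for one replicate.
#'
#' @param cm a [contact_matrix()] with non-overlapping bins.
#' @param window DI window in bp (default 100 kb).
#' @param K quantile levels for DI discretization.
#' @param seed HMM EM seed.
#' @param min_run minimum biased-run length in bins.
#' @param replicate replicate id recorded in the calls.
#' @return list with `di` (profile), `hmm` (fit incl. state path) and
#'   `tads` (a [tad_set()]).
#' @export
call_tads <- function(cm, window = 100000, K = 7L, seed = 1L,
                      min_run = 2L, replicate = 1L) {
  di <- compute_directionality_index(cm, window)
  hmm <- fit_bias_hmm(di, K = K, seed = seed)
  tads <- extract_tads(hmm$path, di$bin_start, cm$bin_size, cm$chrom,
                       min_run = min_run, replicate = replicate)
  list(di = di, hmm = hmm, tads = tads)
}

#' Simulate a complete synthetic 5C experiment
#'
#' Generates primers, per-replicate contact-count tables and the ground
#' truth bundle in one call — the standard entry point for validation
#' runs.
#'
#' @param genome a [toy_genome()].
#' @param model a [planted_tad_model()]; default: six TADs on a 1 Mb
#'   chromosome.
#' @param seed integer seed.
#' @param spacing primer spacing in bp.
#' @return list with `primers`, `tables` (per replicate), `truth` and the
#'   inputs.
#' @export
simulate_fivec_experiment <- function(genome = toy_genome(),
                                      model = NULL,
                                      seed = 1L,
                                      spacing = 10000) {
  if (is.null(model))
    model <- planted_tad_model(default_tad_layout(genome$chrom_names[1L]))
  primers <- generate_primer_set(genome, spacing = spacing)
  tables <- simulate_contact_counts(primers, model, seed = seed)
  list(genome = genome, model = model, primers = primers,
       tables = tables, truth = synthetic_truth(model))
}

#' Replicate pipeline: tables to consensus TADs
#'
#' Normalizes each replicate table, bins it, calls TADs per replicate and
#' derives the consensus.
#'
#' @param tables list of per-replicate [interaction_table()]s.
#' @param primers the `primer_set`.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin size in bp (default 10 kb).
#' @param window DI window in bp.
#' @param tolerance consensus clustering tolerance in bp.
#' @param min_support minimum replicate support.
#' @param seed HMM seed (per-replicate seeds are derived from it).
#' @param norm_factor total-count normalization factor.
#' @return list with per-replicate `calls` and the `consensus`
#'   [tad_set()].
#' @export
consensus_from_tables <- function(tables, primers, chrom_length,
                                  bin_size = 10000, window = 100000,
                                  tolerance = 50000, min_support = 2L,
                                  seed = 1L, norm_factor = 1) {
  calls <- lapply(seq_along(tables), function(r) {
    tab <- normalize_total(tables[[r]], norm_factor)
    cm <- bin_and_smooth(tab, primers, chrom_length = chrom_length,
                         bin_size = bin_size)
    call_tads(cm, window = window, seed = derive_seed(seed, 500L + r),
              replicate = r)
  })
  consensus <- consensus_boundaries(lapply(calls, `[[`, "tads"),
                                    tolerance = tolerance,
                                    min_support = min_support,
                                    bin_size = bin_size)
  list(calls = calls, consensus = consensus)
}

#' Boundary recovery against a planted truth
#'
#' Fraction of planted boundaries with a called boundary within
#' `tolerance`, and the number of called boundaries further than
#' `tolerance` from every planted one (spurious calls).
#'
#' @param truth a [synthetic_truth()] (or data.frame with `chrom`,
#'   `position`).
#' @param called a [tad_set()] or boundary data.frame.
#' @param tolerance matching distance in bp (default 20 kb).
#' @return list with `recovered_fraction`, `n_spurious`, `n_planted`,
#'   `n_called`.
#' @export
boundary_recovery <- function(truth, called, tolerance = 20000) {
  planted <- if (inherits(truth, "synthetic_truth")) truth$boundaries
             else truth
  cb <- if (inherits(called, "tad_set")) tad_boundaries(called) else called
  if (nrow(planted) == 0L) stop("no planted boundaries")
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    same <- cb$position[cb$chrom == planted$chrom[i]]
    length(same) > 0 && any(abs(same - planted$position[i]) <= tolerance)
  }, logical(1))
  spurious <- vapply(seq_len(nrow(cb)), function(i) {
    same <- planted$position[planted$chrom == cb$chrom[i]]
    length(same) == 0 || all(abs(same - cb$position[i]) > tolerance)
  }, logical(1))
  list(recovered_fraction = mean(hit),
       n_spurious = if (nrow(cb)) sum(spurious) else 0L,
       n_planted = nrow(planted),
       n_called = nrow(cb))
}
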