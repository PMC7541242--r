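#' BED input/output for interval tables
#'
#' Thin wrappers around `rtracklayer`; on-disk BED is 0-based half-open,
#' matching the package-internal convention.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) or an `interval_set`.
#' @param path file path.
#' @return `read_bed` returns an interval data.frame.
#' @export
write_bed <- function(intervals, path) {
  iv <- coerce_intervals(intervals)
  rtracklayer::export(as_granges0(iv), path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a Directionality Index profile as bedGraph
#'
#' @param di a `di_profile`.
#' @param path output path.
#' @export
write_di_bedgraph <- function(di, path) {
  gr <- GenomicRanges::GRanges(
    attr(di, "chrom"),
    IRanges::IRanges(start = di$bin_start + 1,
                     width = attr(di, "bin_size")),
    score = di$di)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Pairwise interaction list input/output (my5C-style upload format)
#'
#' One row per primer pair with both anchor coordinates and the score:
#' `chrom1 start1 end1 chrom2 start2 end2 score` (TSV, 0-based half-open),
#' plus the primer ids for round-tripping.
#'
#' @param table an [interaction_table()] (or pooled table).
#' @param primers the matching `primer_set`.
#' @param path file path.
#' @return `read_interaction_pairs` returns a data.frame with ids and
#'   score.
#' @export
write_interaction_pairs <- function(table, primers, path) {
  p1 <- primers[match(table$fwd_id, primers$id), ]
  p2 <- primers[match(table$rev_id, primers$id), ]
  df <- data.frame(chrom1 = p1$chrom, start1 = p1$start, end1 = p1$end,
                   chrom2 = p2$chrom, start2 = p2$start, end2 = p2$end,
                   fwd_id = table$fwd_id, rev_id = table$rev_id,
                   score = interaction_scores(table))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_interaction_pairs
#' @export
read_interaction_pairs <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Serialize a contact matrix as TSV
#'
#' Long sparse format: `bin1_start bin2_start value`, upper triangle only,
#' with a header line of metadata re-read by `read_matrix_tsv`.
#'
#' @param cm a [contact_matrix()].
#' @param path file path.
#' @export
write_matrix_tsv <- function(cm, path) {
  obs <- which(!is.na(cm$values) & upper.tri(cm$values, diag = TRUE),
               arr.ind = TRUE)
  df <- data.frame(bin1_start = cm$bin_starts[obs[, 1L]],
                   bin2_start = cm$bin_starts[obs[, 2L]],
                   value = cm$values[obs])
  header <- sprintf("# chrom=%s bin_size=%g bin_step=%g n_bins=%d kind=%s",
                    cm$chrom, cm$bin_size, cm$bin_step,
                    length(cm$bin_starts), cm$kind)
  writeLines(header, path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1L]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- as.data.frame(data.table::fread(path, sep = "\t", skip = 1L))
  bin_size <- as.numeric(vals[["bin_size"]])
  bin_step <- as.numeric(vals[["bin_step"]])
  nb <- as.integer(vals[["n_bins"]])
  bin_starts <- seq(0, by = bin_step, length.out = nb)
  m <- matrix(NA_real_, nb, nb)
  i <- match(df$bin1_start, bin_starts)
  j <- match(df$bin2_start, bin_starts)
  m[cbind(i, j)] <- df$value
  m[cbind(j, i)] <- df$value
  contact_matrix(vals[["chrom"]], bin_size, bin_step, bin_starts, m,
                 vals[["kind"]])
}

#' JSON reports
#'
#' `write_expected_model` records the distance-decay expected model;
#' `write_consensus_report` records consensus boundary clusters and the
#' replicate support fraction; `write_truth` dumps a synthetic ground
#' truth bundle.
#'
#' @param x the object to serialize.
#' @param path file path.
#' @export
write_expected_model <- function(x, path) {
  stopifnot(inherits(x, "expected_model"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_expected_model
#' @export
write_consensus_report <- function(x, path) {
  stopifnot(inherits(x, "tad_set"), isTRUE(x$consensus))
  rep <- attr(x, "report")
  jsonlite::write_json(list(tads = x$tads, borders = x$borders,
                            support_fraction = rep$support_fraction,
                            tolerance = rep$tolerance,
                            min_support = rep$min_support,
                            clusters = rep$clusters),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_expected_model
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "synthetic_truth"))
  jsonlite::write_json(
    list(boundaries = x$boundaries,
         tads = x$model$tads,
         feature_enrichment = as.list(x$feature_enrichment),
         active_mean_fpkm = x$active_mean_fpkm,
         inactive_mean_fpkm = x$inactive_mean_fpkm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an expression table as TSV
#' @param expr expression data.frame.
#' @param path file path.
#' @export
write_expression_table <- function(expr, path) {
  data.table::fwrite(expr, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
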