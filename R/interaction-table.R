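#' Construct an interaction table
#'
#' The unit of 5C quantification: one row per forward x reverse primer pair
#' with a raw ligation-junction count and, once normalized, a score on the
#' total-mapped-read scale.
#'
#' @param records data.frame with columns `fwd_id`, `rev_id`, `raw_count`
#'   and optionally `norm_score`.
#' @param total_mapped total number of read pairs assigned to any primer
#'   combination (the normalization denominator).
#' @param normalization_factor factor applied during total-count
#'   normalization, `NA` until [normalize_total()] is run.
#' @param tallies named list of bookkeeping counts
#'   (assigned/ambiguous/unmatched/quality_dropped/short_dropped).
#' @param condition,replicate experiment labels carried into comparisons.
#' @return data.frame of class `interaction_table`.
#' @export
interaction_table <- function(records,
                              total_mapped = sum(records$raw_count),
                              normalization_factor = NA_real_,
                              tallies = NULL,
                              condition = NA_character_,
                              replicate = NA_integer_) {
  stopifnot(is.data.frame(records),
            all(c("fwd_id", "rev_id", "raw_count") %in% names(records)))
  if (any(records$raw_count < 0)) stop("raw counts must be non-negative")
  if (!"norm_score" %in% names(records))
    records$norm_score <- rep(NA_real_, nrow(records))
  structure(records,
            total_mapped = total_mapped,
            normalization_factor = normalization_factor,
            tallies = tallies,
            condition = condition,
            replicate = replicate,
            class = c("interaction_table", "data.frame"))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d primer pairs, %d mapped pairs",
              nrow(x), attr(x, "total_mapped")))
  if (!is.na(attr(x, "normalization_factor")))
    cat(sprintf(", normalized (factor %.4g)",
                attr(x, "normalization_factor")))
  cat("\n")
  NextMethod()
}

#' Total-count normalization of an interaction table
#'
#' Rescales raw junction counts to `raw_count / total_mapped *
#' normalization_factor`. The factor is a per-dataset calibration constant
#' supplied by the analyst (it is recorded in the object's provenance), not
#' something this function derives.
#'
#' @param table an [interaction_table()].
#' @param normalization_factor positive real scaling constant.
#' @return the table with `norm_score` filled in.
#' @export
normalize_total <- function(table, normalization_factor = 1) {
  stopifnot(inherits(table, "interaction_table"))
  if (!is.numeric(normalization_factor) || normalization_factor <= 0)
    stop("normalization_factor must be a positive real")
  total <- attr(table, "total_mapped")
  if (total <= 0) {
    if (nrow(table) > 0) stop("total_mapped is zero but table has records")
    table$norm_score <- numeric(0)
  } else {
    table$norm_score <- table$raw_count / total * normalization_factor
  }
  attr(table, "normalization_factor") <- normalization_factor
  table
}

# Pull the score column to use downstream: normalized when present,
# otherwise raw counts.
interaction_scores <- function(table) {
  if ("norm_score" %in% names(table) && any(!is.na(table$norm_score)))
    table$norm_score
  else if ("score" %in% names(table))
    table$score
  else
    table$raw_count
}
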