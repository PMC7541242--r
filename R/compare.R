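#' Classify interactions as intra-TAD, inter-TAD or unassigned
#'
#' Anchor-midpoint containment against the consensus TAD intervals: both
#' anchors inside one TAD gives `intra_tad`; anchors in two different TADs
#' of the same chromosome gives `inter_tad`; anchors falling in border
#' gaps or outside all TADs give `unassigned` (excluded from summaries but
#' tallied).
#'
#' @param table an [interaction_table()] or pooled table with `fwd_id`,
#'   `rev_id` and a score column.
#' @param primers `primer_set` for anchor coordinates.
#' @param tads a [tad_set()] (typically the consensus) or a data.frame
#'   with `chrom`, `start`, `end`.
#' @param condition label stored on every row.
#' @return data.frame of class `classified_interactions` with `score`,
#'   `class` and `condition` columns.
#' @export
classify_interactions <- function(table, primers, tads, condition = "WT") {
  validate_primer_set(primers)
  tt <- if (inherits(tads, "tad_set")) tads$tads else tads
  p1 <- primers[match(table$fwd_id, primers$id), ]
  p2 <- primers[match(table$rev_id, primers$id), ]
  if (anyNA(p1$id) || anyNA(p2$id))
    stop("table refers to primers absent from the catalog")
  mid1 <- (p1$start + p1$end) / 2
  mid2 <- (p2$start + p2$end) / 2
  t1 <- t2 <- rep(NA_integer_, nrow(table))
  for (ch in unique(tt$chrom)) {
    s1 <- p1$chrom == ch
    s2 <- p2$chrom == ch
    t1[s1] <- locate_in_tads(ch, mid1[s1], tt)
    t2[s2] <- locate_in_tads(ch, mid2[s2], tt)
  }
  cls <- rep("unassigned", nrow(table))
  both <- !is.na(t1) & !is.na(t2) & p1$chrom == p2$chrom
  cls[both & t1 == t2] <- "intra_tad"
  cls[both & t1 != t2] <- "inter_tad"
  out <- data.frame(fwd_id = table$fwd_id, rev_id = table$rev_id,
                    chrom = p1$chrom, mid1 = mid1, mid2 = mid2,
                    score = interaction_scores(table),
                    class = cls, condition = condition,
                    stringsAsFactors = FALSE)
  structure(out, class = c("classified_interactions", "data.frame"))
}

#' Pool replicate interaction tables by the mean score
#'
#' Per anchor pair, the pooled score is the mean over the replicates in
#' which the pair is present (a pair seen in one replicate keeps its value
#' with presence = 1). Pooling identical replicates is idempotent.
#'
#' @param tables list of [interaction_table()]s (same condition).
#' @return data.frame with `fwd_id`, `rev_id`, `score`, `presence`.
#' @export
pool_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  long <- do.call(rbind, lapply(tables, function(t)
    data.frame(fwd_id = t$fwd_id, rev_id = t$rev_id,
               score = interaction_scores(t), stringsAsFactors = FALSE)))
  key <- paste(long$fwd_id, long$rev_id, sep = "\r")
  agg <- tapply(long$score, key, mean)
  pres <- tapply(long$score, key, length)
  ids <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(fwd_id = ids[, 1L], rev_id = ids[, 2L],
                    score = as.numeric(agg),
                    presence = as.integer(pres),
                    stringsAsFactors = FALSE)
  out <- out[order(out$fwd_id, out$rev_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Notched-boxplot summaries per condition and interaction class
#'
#' Median, quartiles (linear interpolation between order statistics),
#' notch bounds median +/- 1.58 * IQR / sqrt(n) (the standard 95% rule) and
#' Tukey outlier thresholds, computed per (condition, class) group.
#' Unassigned interactions are excluded but counted.
#'
#' @param classified one or more `classified_interactions` frames
#'   (rbind-ed).
#' @return data.frame of class `distribution_summary`, one row per group.
#' @export
summarize_distributions <- function(classified) {
  d <- classified[classified$class != "unassigned", , drop = FALSE]
  groups <- unique(d[, c("condition", "class")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    x <- d$score[d$condition == groups$condition[g] &
                 d$class == groups$class[g]]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3L] - qs[1L]
    half_notch <- 1.58 * iqr / sqrt(length(x))
    data.frame(condition = groups$condition[g], class = groups$class[g],
               n = length(x), q1 = qs[1L], median = qs[2L], q3 = qs[3L],
               notch_low = qs[2L] - half_notch,
               notch_high = qs[2L] + half_notch,
               outlier_low = qs[1L] - 1.5 * iqr,
               outlier_high = qs[3L] + 1.5 * iqr)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unassigned") <- sum(classified$class == "unassigned")
  structure(out, class = c("distribution_summary", "data.frame"))
}

#' Do two conditions' median notches fail to overlap?
#'
#' Non-overlapping notches are the usual visual reading of a median
#' difference at ~95% confidence. An optional Wilcoxon rank-sum test is
#' exposed alongside since the notch rule is a heuristic, not a formal
#' test.
#'
#' @param summaries a `distribution_summary`.
#' @param class interaction class to compare (`"inter_tad"` /
#'   `"intra_tad"`).
#' @param cond_a,cond_b condition labels.
#' @param classified optional classified frame; when given, a two-sided
#'   Wilcoxon rank-sum p-value is added.
#' @return list with `nonoverlap` flag, the two medians and notch bounds,
#'   and optionally `wilcox_p`.
#' @export
notch_separation <- function(summaries, class, cond_a, cond_b,
                             classified = NULL) {
  a <- summaries[summaries$condition == cond_a & summaries$class == class, ]
  b <- summaries[summaries$condition == cond_b & summaries$class == class, ]
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop("conditions not found in summary")
  nonoverlap <- a$notch_low > b$notch_high || b$notch_low > a$notch_high
  out <- list(nonoverlap = nonoverlap,
              median_a = a$median, median_b = b$median,
              notch_a = c(a$notch_low, a$notch_high),
              notch_b = c(b$notch_low, b$notch_high))
  if (!is.null(classified)) {
    xa <- classified$score[classified$condition == cond_a &
                           classified$class == class]
    xb <- classified$score[classified$condition == cond_b &
                           classified$class == class]
    out$wilcox_p <- stats::wilcox.test(xa, xb)$p.value
  }
  out
}
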