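#' FPKM expression category
#'
#' The four heterochromatic-gene expression classes: no expression
#' (< 1 FPKM), low (1-10), moderate (10-50, right-closed) and high
#' (> 50). The published category text leaves (50, 51) unassigned
#' ("moderate 11-50", "high > 51"); the gap is closed at > 50 => high so
#' the classes partition the whole FPKM axis.
#'
#' @param x numeric FPKM values.
#' @return factor with levels no < low < moderate < high.
#' @export
categorize_fpkm <- function(x) {
  out <- ifelse(x < 1, "no",
         ifelse(x <= 10, "low",
         ifelse(x <= 50, "moderate", "high")))
  factor(out, levels = c("no", "low", "moderate", "high"), ordered = TRUE)
}

#' Categorize an expression table and assign genes to TADs
#'
#' Computes the mean FPKM across replicate columns, applies the four-class
#' categorization, and (when TADs are supplied) assigns each gene to the
#' TAD with maximal overlap, flagging genes not fully contained in their
#' TAD as border straddlers.
#'
#' @param expr data.frame with `gene_id`, `chrom`, `start`, `end` and one
#'   or more FPKM replicate columns (names starting `fpkm`).
#' @param tads optional [tad_set()] or TAD data.frame.
#' @return data.frame of class `expression_records` with `mean_fpkm`,
#'   `category`, `tad_id` (row index into the TAD table or `NA`) and
#'   `straddle`.
#' @export
categorize_expression <- function(expr, tads = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(expr)))
  fpkm_cols <- grep("^fpkm", names(expr), value = TRUE)
  if (length(fpkm_cols) == 0L) stop("no fpkm columns found")
  out <- expr
  out$mean_fpkm <- rowMeans(as.matrix(expr[, fpkm_cols, drop = FALSE]))
  out$category <- categorize_fpkm(out$mean_fpkm)
  out$tad_id <- NA_integer_
  out$straddle <- FALSE
  if (!is.null(tads)) {
    tt <- if (inherits(tads, "tad_set")) tads$tads else tads
    for (i in seq_len(nrow(out))) {
      same <- which(tt$chrom == out$chrom[i])
      if (length(same) == 0L) next
      ov <- pmin(tt$end[same], out$end[i]) - pmax(tt$start[same], out$start[i])
      best <- which.max(ov)
      if (ov[best] <= 0) next
      k <- same[best]
      out$tad_id[i] <- k
      out$straddle[i] <- out$start[i] < tt$start[k] || out$end[i] > tt$end[k]
    }
  }
  structure(out, class = c("expression_records", "data.frame"))
}

#' Per-TAD expression-category concordance
#'
#' For each TAD, the modal category of its member genes and the fraction of
#' genes sharing it; the genome-level concordance is the mean of those
#' per-TAD modal fractions. Border straddlers are excluded (and listed),
#' as are TADs without genes.
#'
#' @param records an `expression_records` frame (with TAD assignment).
#' @param tads the [tad_set()] / TAD data.frame the records were assigned
#'   to.
#' @return list with `per_tad` (tad_id, n_genes, modal_category,
#'   modal_fraction), `concordance`, `straddlers` (gene ids) and
#'   `empty_tads` (TAD row indices).
#' @export
tad_expression_concordance <- function(records, tads) {
  tt <- if (inherits(tads, "tad_set")) tads$tads else tads
  straddlers <- records$gene_id[records$straddle]
  use <- records[!records$straddle & !is.na(records$tad_id), , drop = FALSE]
  per_tad <- lapply(sort(unique(use$tad_id)), function(k) {
    cats <- use$category[use$tad_id == k]
    tab <- table(cats)
    data.frame(tad_id = k, n_genes = length(cats),
               modal_category = names(tab)[which.max(tab)],
               modal_fraction = max(tab) / length(cats))
  })
  per_tad <- if (length(per_tad)) do.call(rbind, per_tad) else
    data.frame(tad_id = integer(), n_genes = integer(),
               modal_category = character(), modal_fraction = numeric())
  list(per_tad = per_tad,
       concordance = if (nrow(per_tad)) mean(per_tad$modal_fraction)
                     else NA_real_,
       straddlers = straddlers,
       empty_tads = setdiff(seq_len(nrow(tt)), per_tad$tad_id))
}

#' Set algebra over differentially-expressed gene lists
#'
#' Exact membership combinatorics over gene-id lists (DE calling itself is
#' upstream): per exact-subset counts (UpSet-style), the size of the
#' common intersection and of the union.
#'
#' @param de_lists named list of character vectors of gene ids.
#' @return list with `combinations` (data.frame of subset label and
#'   count), `common` (genes present in every list) and `union_size`.
#' @export
intersect_de_sets <- function(de_lists) {
  stopifnot(length(de_lists) >= 1L, !is.null(names(de_lists)))
  de_lists <- lapply(de_lists, unique)
  all_genes <- unique(unlist(de_lists))
  member <- vapply(de_lists, function(l) all_genes %in% l,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(de_lists)))
  key <- apply(member, 1L, function(row)
    paste(colnames(member)[row], collapse = "+"))
  combos <- as.data.frame(table(combination = key),
                          responseName = "count", stringsAsFactors = FALSE)
  list(combinations = combos,
       common = Reduce(intersect, de_lists),
       union_size = length(all_genes))
}
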