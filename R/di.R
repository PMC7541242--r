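#' Directionality Index profile
#'
#' For every bin, sums the interaction scores to bins within `window` bp
#' upstream (A) and downstream (B) and contrasts them against the expected
#' value under no bias, E = (A + B) / 2, with the chi-squared-style
#' statistic
#'
#'   DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
#'
#' DI is 0 when A = B (including the no-data case A = B = 0, which is
#' flagged). Windows truncated at chromosome ends use the available span.
#' Strongly positive DI (downstream bias) marks the start of a domain,
#' strongly negative DI its end.
#'
#' @param cm a [contact_matrix()] with non-overlapping bins
#'   (`bin_step == bin_size`).
#' @param window window span in bp on each side (default 100 kb); must be a
#'   multiple of the bin size.
#' @return data.frame of class `di_profile` with columns `bin_start`, `A`,
#'   `B`, `E`, `di`, `no_data`; attributes `chrom`, `bin_size`, `window`.
#' @export
compute_directionality_index <- function(cm, window = 100000) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$bin_step != cm$bin_size)
    stop("DI requires non-overlapping bins (bin_step == bin_size)")
  if (window %% cm$bin_size != 0)
    stop("bin_size must divide window")
  nb <- length(cm$bin_starts)
  prof <- data.frame(bin_start = cm$bin_starts,
                     A = 0, B = 0, E = 0, di = 0, no_data = FALSE)
  if (nb == 0L) {
    return(structure(prof, chrom = cm$chrom, bin_size = cm$bin_size,
                     window = window, class = c("di_profile", "data.frame")))
  }
  v <- cm$values
  v[is.na(v)] <- 0
  bs <- cm$bin_starts
  for (i in seq_len(nb)) {
    up <- which(bs < bs[i] & bs[i] - bs <= window)
    dn <- which(bs > bs[i] & bs - bs[i] <= window)
    prof$A[i] <- sum(v[i, up])
    prof$B[i] <- sum(v[i, dn])
  }
  prof$E <- (prof$A + prof$B) / 2
  prof$no_data <- prof$A == 0 & prof$B == 0
  delta <- prof$B - prof$A
  nz <- delta != 0
  prof$di[nz] <- sign(delta[nz]) *
    ((prof$A[nz] - prof$E[nz])^2 / prof$E[nz] +
     (prof$B[nz] - prof$E[nz])^2 / prof$E[nz])
  structure(prof, chrom = cm$chrom, bin_size = cm$bin_size, window = window,
            class = c("di_profile", "data.frame"))
}
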