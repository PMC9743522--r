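# expected (balanced) count per diagonal separation for one chromosome.
# unmasked: logical over the chromosome's bins; returns list(expected_by_sep,
# n_pairs_by_sep) indexed by separation + 1 (separation 0 = diagonal).
chrom_expected <- function(counts_df, unmasked, nbins) {
  u <- as.numeric(unmasked)
  n_pairs <- vapply(0:(nbins - 1L), function(d) {
    if (d == 0L) sum(u) else sum(u[seq_len(nbins - d)] * u[seq_len(nbins - d) + d])
  }, 0)
  sums <- numeric(nbins)
  if (nrow(counts_df) > 0L) {
    sep <- counts_df$j - counts_df$i
    r <- rowsum(counts_df$value, sep, reorder = TRUE)
    sums[as.integer(rownames(r)) + 1L] <- r[, 1L]
  }
  expected <- ifelse(n_pairs > 0, sums / n_pairs, NA_real_)
  list(expected = expected, n_pairs = n_pairs)
}

#' Observed/expected transformation
#'
#' Divides each cis contact by the mean (balanced) count at the same diagonal
#' separation within its chromosome, removing the distance-decay trend. Pairs
#' at a separation whose expected value is zero (or undefined because all bins
#' are masked) are flagged missing and dropped, never divided. Trans entries
#' carry no separation and are excluded from the output.
#'
#' @param mat A [contact_matrix()]; must carry weights when `use_weights`.
#' @param use_weights Use balanced counts (`count * w_i * w_j`); masked bins
#'   are then excluded.
#' @return A [contact_matrix()] whose `count` column holds O/E ratios, with
#'   attribute `n_dropped` (entries flagged missing).
#' @export
observed_expected <- function(mat, use_weights = FALSE) {
  if (use_weights && is.null(mat$weights))
    stop_fmt("use_weights = TRUE requires a balanced matrix; run balance() first")
  bins <- mat$bins
  out <- list()
  n_dropped <- 0L
  for (ch in unique(bins$chrom)) {
    sub <- bins[bins$chrom == ch, , drop = FALSE]
    lo <- min(sub$bin); hi <- max(sub$bin)
    nb <- hi - lo + 1L
    e <- mat$entries
    cis <- e[e$bin1 >= lo & e$bin2 <= hi & e$bin1 <= hi, , drop = FALSE]
    cis <- cis[cis$bin2 >= lo, , drop = FALSE]
    unmasked <- if (use_weights) !is.na(mat$weights[lo:hi]) else rep(TRUE, nb)
    val <- cis$count
    if (use_weights) val <- val * mat$weights[cis$bin1] * mat$weights[cis$bin2]
    keep <- !is.na(val)
    cdf <- data.frame(i = cis$bin1[keep] - lo, j = cis$bin2[keep] - lo,
                      value = val[keep])
    n_dropped <- n_dropped + sum(!keep)
    ex <- chrom_expected(cdf, unmasked, nb)
    expd <- ex$expected[cdf$j - cdf$i + 1L]
    ok <- !is.na(expd) & expd > 0
    n_dropped <- n_dropped + sum(!ok)
    out[[ch]] <- data.frame(bin1 = cdf$i[ok] + lo, bin2 = cdf$j[ok] + lo,
                            count = cdf$value[ok] / expd[ok])
  }
  res <- contact_matrix(bins, do.call(rbind, out), weights = mat$weights,
                        sample = mat$sample, assembly = mat$assembly)
  attr(res, "n_dropped") <- n_dropped
  attr(res, "kind") <- "oe"
  res
}

# dense symmetric O/E matrix for one chromosome; masked rows/cols NA.
# returns list(oe = matrix, unmasked = logical, bins = chromosome bin rows)
oe_dense <- function(mat, chrom, use_weights = TRUE) {
  bins <- mat$bins
  sub <- bins[bins$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0L) stop_fmt("chromosome '%s' not in matrix", chrom)
  lo <- min(sub$bin); hi <- max(sub$bin)
  nb <- hi - lo + 1L
  unmasked <- if (use_weights) {
    if (is.null(mat$weights)) stop_fmt("matrix has no balancing weights")
    !is.na(mat$weights[lo:hi])
  } else rep(TRUE, nb)
  e <- mat$entries
  cis <- e[e$bin1 >= lo & e$bin1 <= hi & e$bin2 >= lo & e$bin2 <= hi, , drop = FALSE]
  val <- cis$count
  if (use_weights) val <- val * mat$weights[cis$bin1] * mat$weights[cis$bin2]
  keep <- !is.na(val)
  cdf <- data.frame(i = cis$bin1[keep] - lo, j = cis$bin2[keep] - lo, value = val[keep])
  ex <- chrom_expected(cdf, unmasked, nb)
  M <- matrix(0, nb, nb)
  if (nrow(cdf) > 0L) {
    M[cbind(cdf$i + 1L, cdf$j + 1L)] <- cdf$value
    M[cbind(cdf$j + 1L, cdf$i + 1L)] <- cdf$value
  }
  E <- matrix(NA_real_, nb, nb)
  for (d in 0:(nb - 1L)) {
    ed <- ex$expected[d + 1L]
    if (is.na(ed)) next
    idx <- seq_len(nb - d)
    E[cbind(idx, idx + d)] <- ed
    E[cbind(idx + d, idx)] <- ed
  }
  OE <- ifelse(!is.na(E) & E > 0, M / E, NA_real_)
  OE[!unmasked, ] <- NA_real_
  OE[, !unmasked] <- NA_real_
  list(oe = OE, unmasked = unmasked, bins = sub)
}
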