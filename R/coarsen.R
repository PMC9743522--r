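#' Breakpoint-anchored coarsening of a contact matrix
#'
#' Sums fine bins into coarse bins of width `factor` times the fine width. The
#' coarse bin edges of the anchor chromosome are phased so that one boundary
#' coincides exactly with `anchor_position`, so that the regions immediately
#' upstream and downstream of a breakpoint of interest (e.g. the kept
#' C-terminal and the lost N-terminal of a fused gene) fall into different
#' coarse bins. The first coarse bin of the anchor chromosome is short when
#' the anchor is not itself a multiple of the coarse width. The genome-wide
#' total count is conserved exactly.
#'
#' @param mat A fine-resolution [contact_matrix()] on unphased bins.
#' @param factor Integer aggregation factor (coarse = factor x fine).
#' @param anchor_chrom,anchor_position Phasing anchor; the position must be
#'   aligned to the fine bin grid.
#' @return A [contact_matrix()] at coarse resolution (weights dropped).
#' @export
coarsen_anchored <- function(mat, factor, anchor_chrom, anchor_position) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop_fmt("factor must be a positive integer")
  fine <- attr(mat$bins, "bin_size")
  if (anchor_position %% fine != 0)
    stop_fmt(paste("anchor position %s is not aligned to the %s bp fine grid;",
                   "snap it to a fine bin boundary first"),
             format(anchor_position, big.mark = ","), format(fine, big.mark = ","))
  cl <- attr(mat$bins, "chrom_lengths")
  coarse_bins <- bin_table(cl, fine * factor,
                           anchor_chrom = anchor_chrom, anchor_pos = anchor_position)
  map <- locate_bins(coarse_bins, mat$bins$chrom, mat$bins$start)
  e <- mat$entries
  entries <- if (nrow(e) > 0L)
    data.frame(bin1 = map[e$bin1], bin2 = map[e$bin2], count = e$count)
  else NULL
  contact_matrix(coarse_bins, entries, sample = mat$sample, assembly = mat$assembly)
}
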