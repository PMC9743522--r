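#' Bin table
#'
#' Tile a genome into uniform-width bins. Bins are 0-based half-open and tile
#' each chromosome without gaps or overlaps; the last bin of a chromosome may
#' be short. When an anchor is given, the bin edges of the anchor chromosome
#' are phased so that one boundary falls exactly at `anchor_pos` (the first bin
#' of that chromosome is then short). This phasing is what separates the kept
#' and lost gene terminals into different coarse bins.
#'
#' @param chrom_lengths Named numeric vector (or data.frame with `chrom`,
#'   `length`) of chromosome lengths in bp, in the desired order.
#' @param bin_size Bin width in bp.
#' @param anchor_chrom,anchor_pos Optional phasing anchor.
#' @return data.frame with columns `chrom`, `start`, `end`, `bin` (dense
#'   1-based index sorted by chromosome order then start), with attributes
#'   `bin_size`, `chrom_lengths` and `anchor`.
#' @export
bin_table <- function(chrom_lengths, bin_size, anchor_chrom = NULL, anchor_pos = NULL) {
  chrom_lengths <- as_chrom_lengths(chrom_lengths)
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) stop_fmt("bin_size must be > 0")
  if (!is.null(anchor_chrom)) {
    if (is.null(anchor_pos)) stop_fmt("anchor_pos required with anchor_chrom")
    if (!anchor_chrom %in% names(chrom_lengths))
      stop_fmt("anchor chromosome '%s' not in chrom_lengths", anchor_chrom)
    if (anchor_pos < 0 || anchor_pos > chrom_lengths[[anchor_chrom]])
      stop_fmt("anchor position %s outside chromosome '%s'", anchor_pos, anchor_chrom)
  }
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (!is.null(anchor_chrom) && ch == anchor_chrom) {
      off <- anchor_pos %% bin_size
      edges <- c(0, seq(off, len, by = bin_size), len)
    } else {
      edges <- c(seq(0, len, by = bin_size), len)
    }
    edges <- sort(unique(edges[edges >= 0 & edges <= len]))
    data.frame(chrom = ch, start = utils::head(edges, -1),
               end = utils::tail(edges, -1), stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, rows)
  b$bin <- seq_len(nrow(b))
  rownames(b) <- NULL
  attr(b, "bin_size") <- bin_size
  attr(b, "chrom_lengths") <- chrom_lengths
  attr(b, "anchor") <- if (is.null(anchor_chrom)) NULL else
    list(chrom = anchor_chrom, pos = as.numeric(anchor_pos))
  b
}

# vectorized (chrom, position) -> bin index lookup; NA outside the genome
locate_bins <- function(bins, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sub <- bins[bins$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(sub) == 0L) next
    k <- findInterval(pos[sel], sub$start)
    bad <- pos[sel] < 0 | pos[sel] >= max(sub$end) | k == 0L
    k[bad] <- NA_integer_
    out[sel] <- sub$bin[k]
  }
  out
}

same_bins <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

# bins (indices) of `bins` overlapping a genomic interval
bins_overlapping <- function(bins, interval) {
  interval <- as_gi(interval)
  bins$bin[bins$chrom == interval$chrom &
           bins$start < interval$end & bins$end > interval$start]
}
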