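#' Genomic interval
#'
#' A minimal 0-based half-open genomic interval. All coordinates inside the
#' package use this convention (BED-style): `start` is included, `end` is not.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (>= 0).
#' @param end 0-based exclusive end (> start).
#' @return An object of class `genomic_interval`.
#' @examples
#' gi("chr7", 140710000, 140790000)
#' @export
gi <- function(chrom, start, end) {
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop_fmt("gi() builds a single interval; got vector input")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 0) stop_fmt("interval start must be >= 0 (got %s)", start)
  if (is.na(end) || end <= start)
    stop_fmt("interval end must exceed start (got [%s, %s))", start, end)
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%s, %s)  width=%s\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

gi_width <- function(x) x$end - x$start

# do two intervals overlap (same chromosome, any shared base)?
gi_overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

as_gi <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x)))
    return(gi(x$chrom, x$start, x$end))
  stop_fmt("cannot interpret object of class '%s' as a genomic interval",
           paste(class(x), collapse = "/"))
}
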