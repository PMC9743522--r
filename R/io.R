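#' Read a contact matrix from COO text
#'
#' The COO text dialect is deliberately trivial and diff-stable: header lines
#' `#bin_size<TAB>N`, one `#chrom<TAB>name<TAB>length` per chromosome (in
#' order), an optional `#anchor<TAB>chrom<TAB>pos` phasing line, then one
#' `i<TAB>j<TAB>count` triple per stored entry with 0-based bin indices.
#' Entries with `i > j` are folded to the upper triangle and duplicate pairs
#' summed, so any symmetric dump reads back to canonical form.
#'
#' @param path File path.
#' @return A [contact_matrix()].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(hdr, "\t", fixed = TRUE)
  keys <- vapply(fields, `[`, "", 1L)
  bs_line <- fields[keys == "#bin_size"]
  if (length(bs_line) != 1L) stop_fmt("%s: missing #bin_size header", path)
  bin_size <- as.numeric(bs_line[[1L]][2L])
  if (!is.finite(bin_size) || bin_size <= 0)
    stop_fmt("%s: invalid bin size '%s'", path, bs_line[[1L]][2L])
  ch <- fields[keys == "#chrom"]
  if (length(ch) == 0L) stop_fmt("%s: no #chrom headers", path)
  chrom_lengths <- stats::setNames(
    as.numeric(vapply(ch, `[`, "", 3L)),
    vapply(ch, `[`, "", 2L))
  if (anyNA(chrom_lengths)) stop_fmt("%s: malformed #chrom header", path)
  an <- fields[keys == "#anchor"]
  if (length(an) > 0L) {
    bins <- bin_table(chrom_lengths, bin_size,
                      anchor_chrom = an[[1L]][2L],
                      anchor_pos = as.numeric(an[[1L]][3L]))
  } else {
    bins <- bin_table(chrom_lengths, bin_size)
  }
  if (length(body) > 0L) {
    m <- utils::read.table(text = body, sep = "\t", col.names = c("i", "j", "count"),
                           colClasses = c("integer", "integer", "numeric"))
    if (any(m$count < 0)) stop_fmt("%s: negative contact counts", path)
    entries <- data.frame(bin1 = m$i + 1L, bin2 = m$j + 1L, count = m$count)
  } else entries <- NULL
  contact_matrix(bins, entries, sample = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a contact matrix as canonical COO text
#'
#' Writes the canonical form read back losslessly by [read_matrix()]:
#' upper-triangle entries sorted by `(i, j)`, 0-based indices, integer counts
#' printed without decimals. Balancing weights are not stored here; use
#' [write_bedgraph()] for per-bin vectors.
#'
#' @param mat A [contact_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  bins <- mat$bins
  cl <- attr(bins, "chrom_lengths")
  anchor <- attr(bins, "anchor")
  hdr <- c(sprintf("#bin_size\t%s", format_count(attr(bins, "bin_size"))),
           sprintf("#chrom\t%s\t%s", names(cl), format_count(unname(cl))))
  if (!is.null(anchor))
    hdr <- c(hdr, sprintf("#anchor\t%s\t%s", anchor$chrom, format_count(anchor$pos)))
  e <- mat$entries
  body <- if (nrow(e) > 0L)
    sprintf("%d\t%d\t%s", e$bin1 - 1L, e$bin2 - 1L, format_count(e$count))
  else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a per-bin vector as bedGraph
#'
#' @param bins A [bin_table()].
#' @param values Numeric vector, one value per bin; `NA` bins are omitted.
#' @param path Output path.
#' @param track_name Optional track line name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path, track_name = NULL) {
  stopifnot(length(values) == nrow(bins))
  keep <- !is.na(values)
  lines <- sprintf("%s\t%s\t%s\t%s", bins$chrom[keep],
                   format_count(bins$start[keep]), format_count(bins$end[keep]),
                   sprintf("%.6g", values[keep]))
  if (!is.null(track_name))
    lines <- c(sprintf("track type=bedGraph name=\"%s\"", track_name), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file as a per-bin vector over a bin table
#'
#' @param path bedGraph path (track lines ignored).
#' @param bins A [bin_table()]; values are assigned to the bin containing each
#'   record's start. Bins without a record get `NA`.
#' @return Numeric vector of length `nrow(bins)`.
#' @export
read_bedgraph <- function(path, bins) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  out <- rep(NA_real_, nrow(bins))
  if (length(lines) == 0L) return(out)
  d <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  idx <- locate_bins(bins, d$chrom, d$start)
  ok <- !is.na(idx)
  out[idx[ok]] <- d$value[ok]
  out
}
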