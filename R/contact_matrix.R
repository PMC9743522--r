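#' Sparse binned contact matrix
#'
#' The substrate of all Hi-C operations: a symmetric genome-wide contact map
#' stored as its upper triangle over a [bin_table()]. Entries given with
#' `bin1 > bin2` are folded onto the upper triangle and duplicate pairs are
#' summed, so the matrix is symmetric by construction. Optional per-bin
#' balancing weights (from [balance()]) are carried alongside; masked bins
#' have weight `NA`.
#'
#' @param bins A [bin_table()].
#' @param entries data.frame with columns `bin1`, `bin2` (1-based bin indices)
#'   and `count` (>= 0). May be empty.
#' @param weights Optional numeric vector of per-bin balancing weights
#'   (`NA` = masked), length `nrow(bins)`.
#' @param sample,assembly Metadata labels.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, entries = NULL, weights = NULL,
                           sample = NA_character_, assembly = NA_character_) {
  if (is.null(attr(bins, "bin_size"))) stop_fmt("bins must come from bin_table()")
  n <- nrow(bins)
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.frame(bin1 = integer(), bin2 = integer(), count = numeric())
  } else {
    stopifnot(all(c("bin1", "bin2", "count") %in% names(entries)))
    if (any(!is.finite(entries$count)) || any(entries$count < 0))
      stop_fmt("contact counts must be finite and >= 0")
    if (any(entries$bin1 < 1L) || any(entries$bin1 > n) ||
        any(entries$bin2 < 1L) || any(entries$bin2 > n))
      stop_fmt("bin indices out of range 1..%d", n)
    entries <- fold_entries(entries, n)
  }
  if (!is.null(weights)) {
    if (length(weights) != n) stop_fmt("weights must have one value per bin")
    if (any(!is.na(weights) & weights <= 0))
      stop_fmt("balancing weights must be positive or NA (masked)")
  }
  structure(list(bins = bins, entries = entries, weights = weights,
                 sample = sample, assembly = assembly),
            class = "contact_matrix")
}

# fold to upper triangle (bin1 <= bin2) and sum duplicates; canonical order
fold_entries <- function(entries, n_bins) {
  b1 <- pmin(entries$bin1, entries$bin2)
  b2 <- pmax(entries$bin1, entries$bin2)
  key <- (as.numeric(b1) - 1) * n_bins + as.numeric(b2)
  tot <- rowsum(as.numeric(entries$count), key, reorder = TRUE)
  keys <- as.numeric(rownames(tot))
  data.frame(bin1 = as.integer((keys - 1) %/% n_bins + 1),
             bin2 = as.integer((keys - 1) %% n_bins + 1),
             count = as.numeric(tot[, 1L]))
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%s bp) over %d chromosome(s), %d entries, total %s\n",
              nrow(x$bins), format(attr(x$bins, "bin_size"), big.mark = ","),
              length(unique(x$bins$chrom)), nrow(x$entries),
              format(total_count(x), big.mark = ",")))
  if (!is.null(x$weights))
    cat(sprintf("  balanced: %d/%d bins unmasked\n",
                sum(!is.na(x$weights)), length(x$weights)))
  invisible(x)
}

#' Genome-wide total contact count
#'
#' Each unordered bin pair (including the diagonal) is counted once.
#' @param mat A [contact_matrix()].
#' @return Numeric scalar.
#' @export
total_count <- function(mat) sum(mat$entries$count)

#' Per-bin (weighted) row sums of a contact matrix
#'
#' Row sums of the full symmetric matrix, the diagonal counted once. With
#' `use_weights = TRUE`, counts are first multiplied by `w_i * w_j` and bins
#' with `NA` weight return `NA`.
#'
#' @param mat A [contact_matrix()].
#' @param use_weights Apply balancing weights.
#' @return Numeric vector, one value per bin.
#' @export
row_sums <- function(mat, use_weights = FALSE) {
  n <- nrow(mat$bins)
  e <- mat$entries
  v <- e$count
  if (use_weights) {
    if (is.null(mat$weights)) stop_fmt("matrix has no balancing weights")
    v <- v * mat$weights[e$bin1] * mat$weights[e$bin2]
  }
  s <- numeric(n)
  if (nrow(e) > 0L) {
    off <- e$bin1 != e$bin2
    idx <- c(e$bin1, e$bin2[off])
    val <- c(v, v[off])
    keep <- !is.na(val)
    if (any(keep)) {
      r <- rowsum(val[keep], idx[keep], reorder = TRUE)
      s[as.integer(rownames(r))] <- r[, 1L]
    }
  }
  if (use_weights) s[is.na(mat$weights)] <- NA_real_
  s
}

#' Sum two contact matrices on the same bin table
#' @param a,b [contact_matrix()] objects on identical bins.
#' @return A [contact_matrix()] with per-pair summed counts.
#' @export
add_matrices <- function(a, b) {
  if (!same_bins(a$bins, b$bins)) stop_fmt("matrices are on different bin tables")
  contact_matrix(a$bins, rbind(a$entries, b$entries), sample = a$sample,
                 assembly = a$assembly)
}

#' Attach balancing weights to a matrix
#' @param mat A [contact_matrix()].
#' @param weights Per-bin weights as returned by [balance()].
#' @return The matrix with `weights` set.
#' @export
set_weights <- function(mat, weights) {
  contact_matrix(mat$bins, mat$entries, weights = weights,
                 sample = mat$sample, assembly = mat$assembly)
}
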