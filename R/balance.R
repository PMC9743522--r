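#' Balance a contact matrix by iterative correction
#'
#' Computes per-bin multiplicative weights such that the weighted row sums of
#' the symmetric matrix are uniform, removing coverage and accessibility bias.
#' Bins in the lowest coverage quantile (and all zero-coverage bins) are
#' masked and receive `NA` weights. This is the standard iterative-correction
#' scheme; any externally computed per-bin weights (e.g. from a karyotype-aware
#' model) can be attached with [set_weights()] under the same contract.
#'
#' The balanced count of a pair `(i, j)` is `count * w_i * w_j`.
#'
#' @param mat A non-empty [contact_matrix()].
#' @param max_iter Maximum number of correction sweeps.
#' @param tol Convergence threshold on the relative variance
#'   `var(s) / mean(s)^2` of unmasked weighted row sums.
#' @param min_coverage_quantile Bins with raw coverage strictly below this
#'   quantile of per-bin coverage are masked (default: drop the lowest 2%).
#' @return Numeric weight vector (length = number of bins, `NA` at masked
#'   bins), normalized to unit mean over unmasked bins, with attributes
#'   `converged`, `iterations`, `rel_var` and `masked`. Non-convergence
#'   raises a warning and is flagged in the attributes, never silent.
#' @export
balance <- function(mat, max_iter = 200L, tol = 1e-5, min_coverage_quantile = 0.02) {
  if (nrow(mat$entries) == 0L) stop_fmt("cannot balance an empty matrix")
  n <- nrow(mat$bins)
  cov <- row_sums(mat)
  thr <- stats::quantile(cov, min_coverage_quantile, names = FALSE, type = 7)
  masked <- cov == 0 | cov < thr
  if (all(masked)) stop_fmt("all %d bins masked at coverage quantile %.3g",
                            n, min_coverage_quantile)
  e <- mat$entries
  keep <- !masked[e$bin1] & !masked[e$bin2]
  e <- e[keep, , drop = FALSE]
  off <- e$bin1 != e$bin2
  idx <- c(e$bin1, e$bin2[off])
  dup <- c(seq_len(nrow(e)), which(off))

  w <- rep(1, n)
  rel_var <- Inf
  iter <- 0L
  repeat {
    v <- e$count * w[e$bin1] * w[e$bin2]
    s <- numeric(n)
    r <- rowsum(v[dup], idx, reorder = TRUE)
    s[as.integer(rownames(r))] <- r[, 1L]
    su <- s[!masked]
    m <- mean(su)
    if (m == 0) stop_fmt("all unmasked bins have zero weighted coverage")
    rel_var <- mean((su / m - 1)^2)
    if (rel_var <= tol || iter >= max_iter) break
    f <- s / m
    f[masked | f == 0] <- 1
    w <- w / f
    iter <- iter + 1L
  }
  converged <- rel_var <= tol
  if (!converged)
    warn_fmt("balancing did not converge in %d iterations (rel_var = %.3g)",
             iter, rel_var)
  w <- w / mean(w[!masked])
  w[masked] <- NA_real_
  attr(w, "converged") <- converged
  attr(w, "iterations") <- iter
  attr(w, "rel_var") <- rel_var
  attr(w, "masked") <- masked
  w
}
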