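#' A/B compartment score for one chromosome
#'
#' Computes the per-bin compartment score as an eigenvector of the Pearson
#' correlation matrix of the cis observed/expected map, scaled by the square
#' root of its eigenvalue. Positive scores are A (open, active) compartment,
#' negative scores are B (closed, repressed). Because the sign of an
#' eigenvector is arbitrary, the global sign is fixed so that the score
#' correlates non-negatively with `orientation_track` (a per-bin reference
#' signal: the planted A-density on simulated data, gene density or GC content
#' on real data — the orientation is an explicit input, never guessed).
#'
#' The top `n_eigs` eigenvectors are examined and the one most correlated (in
#' absolute value) with the orientation track is selected; when that is not
#' the leading eigenvector (as can happen when the first component tracks
#' karyotype on aneuploid samples) the result is flagged via the
#' `eigen_index`/`eigen_flagged` attributes.
#'
#' @param mat A balanced [contact_matrix()] (or any matrix with
#'   `use_weights = FALSE`).
#' @param chrom Chromosome to score (needs >= `min_bins` unmasked bins).
#' @param orientation_track Numeric vector, one value per bin of `chrom`.
#' @param use_weights Use balanced counts.
#' @param n_eigs Number of leading eigenvectors to consider.
#' @param min_bins Minimum unmasked bins required.
#' @return A `compartment_track`: data.frame with `chrom`, `start`, `end`,
#'   `score` (NA at masked bins) and `label` (`"A"`, `"B"` or
#'   `"unassigned"`), with attributes `sample`, `eigen_index`,
#'   `eigen_flagged`, `eigenvalues` and `orientation_cor`.
#' @export
compartment_score <- function(mat, chrom, orientation_track, use_weights = TRUE,
                              n_eigs = 3L, min_bins = 20L) {
  dd <- oe_dense(mat, chrom, use_weights = use_weights)
  nb <- nrow(dd$bins)
  if (length(orientation_track) != nb)
    stop_fmt("orientation_track must have one value per bin of '%s' (%d)", chrom, nb)
  sub <- which(dd$unmasked)
  if (length(sub) < min_bins)
    stop_fmt("chromosome '%s' has %d unmasked bins (< %d required)",
             chrom, length(sub), min_bins)
  OE <- dd$oe[sub, sub, drop = FALSE]
  sds <- apply(OE, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop_fmt("degenerate O/E correlation matrix on chromosome '%s': %d constant rows",
             chrom, sum(!is.finite(sds) | sds == 0))
  C <- stats::cor(OE, use = "pairwise.complete.obs")
  if (anyNA(C))
    stop_fmt("degenerate O/E correlation matrix on chromosome '%s': undefined entries",
             chrom)
  eg <- eigen(C, symmetric = TRUE)
  k <- min(n_eigs, ncol(eg$vectors))
  ot <- orientation_track[sub]
  ors <- vapply(seq_len(k), function(i) {
    r <- suppressWarnings(stats::cor(eg$vectors[, i], ot))
    if (is.na(r)) 0 else r
  }, 0)
  sel <- which.max(abs(ors))
  sgn <- if (ors[sel] < 0) -1 else 1
  vec <- eg$vectors[, sel] * sqrt(max(eg$values[sel], 0)) * sgn
  score <- rep(NA_real_, nb)
  score[sub] <- vec
  track <- data.frame(chrom = dd$bins$chrom, start = dd$bins$start,
                      end = dd$bins$end, score = score,
                      label = ifelse(is.na(score), "unassigned",
                                     ifelse(score > 0, "A",
                                            ifelse(score < 0, "B", "unassigned"))),
                      stringsAsFactors = FALSE)
  attr(track, "sample") <- mat$sample
  attr(track, "eigen_index") <- sel
  attr(track, "eigen_flagged") <- sel != 1L
  attr(track, "eigenvalues") <- eg$values[seq_len(k)]
  attr(track, "orientation_cor") <- abs(ors[sel])
  class(track) <- c("compartment_track", "data.frame")
  track
}

#' Convert planted A/B labels to an orientation track
#' @param labels Character vector of `"A"`/`"B"` per bin.
#' @return Numeric vector: +1 for A, -1 for B, NA otherwise.
#' @export
a_density_track <- function(labels) {
  ifelse(labels == "A", 1, ifelse(labels == "B", -1, NA_real_))
}

#' Compare compartment tracks across samples
#'
#' Pairwise Pearson correlation of compartment scores over bins unmasked in
#' both tracks (pairwise-complete observations), optionally restricted to a
#' region, followed by average-linkage hierarchical clustering on the
#' `1 - correlation` distance. Pairs sharing fewer than 2 unmasked bins are
#' flagged missing with a warning; samples involved in missing pairs are
#' excluded from the linkage tree (but kept in the correlation matrix).
#'
#' @param tracks List of `compartment_track`s on a shared bin table (>= 2).
#' @param region Optional [gi()] restricting the compared bins.
#' @return A `sample_similarity`: list with `samples`, `correlation`
#'   (symmetric, unit diagonal), `linkage` (an [stats::hclust] tree) and
#'   `excluded` (samples dropped from the linkage).
#' @export
compare_tracks <- function(tracks, region = NULL) {
  if (length(tracks) < 2L) stop_fmt("need at least 2 tracks to compare")
  b0 <- tracks[[1L]]
  for (t in tracks[-1L])
    if (!(nrow(t) == nrow(b0) && all(t$chrom == b0$chrom) && all(t$start == b0$start)))
      stop_fmt("tracks do not share a bin table")
  samples <- vapply(seq_along(tracks), function(i)
    attr(tracks[[i]], "sample") %||% sprintf("sample_%d", i), "")
  samples[is.na(samples)] <- sprintf("sample_%d", which(is.na(samples)))
  S <- vapply(tracks, function(t) t$score, numeric(nrow(b0)))
  if (!is.null(region)) {
    region <- as_gi(region)
    keep <- b0$chrom == region$chrom & b0$start < region$end & b0$end > region$start
    S <- S[keep, , drop = FALSE]
  }
  colnames(S) <- samples
  C <- suppressWarnings(stats::cor(S, use = "pairwise.complete.obs"))
  diag(C) <- 1
  excluded <- character()
  if (anyNA(C)) {
    warn_fmt("%d sample pair(s) share < 2 unmasked bins; excluded from linkage",
             sum(is.na(C[upper.tri(C)])))
    bad <- colSums(is.na(C))
    while (anyNA(C[!(samples %in% excluded), !(samples %in% excluded)])) {
      cand <- samples[!(samples %in% excluded)]
      sub <- C[cand, cand, drop = FALSE]
      excluded <- c(excluded, cand[which.max(colSums(is.na(sub)))])
    }
  }
  keep <- setdiff(samples, excluded)
  linkage <- if (length(keep) >= 2L)
    stats::hclust(stats::as.dist(1 - C[keep, keep]), method = "average")
  else NULL
  structure(list(samples = samples, correlation = C, linkage = linkage,
                 excluded = excluded),
            class = "sample_similarity")
}

#' @export
print.sample_similarity <- function(x, ...) {
  cat(sprintf("sample_similarity over %d samples", length(x$samples)))
  if (length(x$excluded)) cat(sprintf(" (%d excluded from linkage)", length(x$excluded)))
  cat("\n")
  print(round(x$correlation, 3))
  invisible(x)
}

#' Write a sample similarity matrix as TSV
#' @param sim A `sample_similarity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  utils::write.table(round(sim$correlation, 6), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Export the linkage tree as Newick
#' @param sim A `sample_similarity` with a linkage tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_newick <- function(sim, path) {
  if (is.null(sim$linkage)) stop_fmt("no linkage tree (too few comparable samples)")
  ape::write.tree(ape::as.phylo(sim$linkage), file = path)
  invisible(path)
}

#' Summarize a compartment track over an interval
#'
#' Mean score and majority label over the track bins overlapping an interval;
#' used e.g. to ask whether both partners of a fusion lie in open (A)
#' chromatin.
#'
#' @param track A `compartment_track`.
#' @param interval A [gi()] on the track's chromosome.
#' @return list with `mean_score`, `label` (majority; `"unassigned"` when no
#'   unmasked bin overlaps) and `n_bins`.
#' @export
compartment_at <- function(track, interval) {
  interval <- as_gi(interval)
  if (!interval$chrom %in% track$chrom)
    stop_fmt("interval chromosome '%s' is not the track's chromosome", interval$chrom)
  ov <- track$chrom == interval$chrom & track$start < interval$end &
    track$end > interval$start & !is.na(track$score)
  if (!any(ov)) return(list(mean_score = NA_real_, label = "unassigned", n_bins = 0L))
  labs <- track$label[ov]
  tab <- table(labs)
  label <- names(tab)[which.max(tab)]
  if (sum(tab == max(tab)) > 1L) label <- "unassigned"
  list(mean_score = mean(track$score[ov]), label = label, n_bins = sum(ov))
}
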