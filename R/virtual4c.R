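#' Viewpoint anchors for a target gene
#'
#' The three viewpoint intervals of the virtual 4C design: the kept C-terminal
#' region, the lost N-terminal region, and the full-gene background used as
#' normalization denominator. The two terminals must be disjoint, adjacent,
#' and partition the background exactly; their shared boundary is the
#' breakpoint anchor used to phase coarse bins ([coarsen_anchored()]).
#'
#' @param gene Gene name.
#' @param c_terminal,n_terminal [gi()] intervals on one chromosome.
#' @param background Optional [gi()]; defaults to the union of the terminals
#'   and must equal it exactly when supplied.
#' @return An `anchor_set`.
#' @export
anchor_set <- function(gene, c_terminal, n_terminal, background = NULL) {
  c_terminal <- as_gi(c_terminal); n_terminal <- as_gi(n_terminal)
  if (c_terminal$chrom != n_terminal$chrom)
    stop_fmt("anchors must lie on one chromosome")
  if (c_terminal$end == n_terminal$start) {
    boundary <- c_terminal$end
    union_iv <- gi(c_terminal$chrom, c_terminal$start, n_terminal$end)
  } else if (n_terminal$end == c_terminal$start) {
    boundary <- n_terminal$end
    union_iv <- gi(c_terminal$chrom, n_terminal$start, c_terminal$end)
  } else {
    stop_fmt("C- and N-terminal anchors must be disjoint and adjacent (a partition of the gene)")
  }
  if (is.null(background)) background <- union_iv
  background <- as_gi(background)
  if (!(background$chrom == union_iv$chrom && background$start == union_iv$start &&
        background$end == union_iv$end))
    stop_fmt("background must equal the union of the two terminal anchors exactly")
  structure(list(gene = gene, c_terminal = c_terminal, n_terminal = n_terminal,
                 background = background, boundary = boundary),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set for %s on %s (boundary %s)\n", x$gene,
              x$background$chrom, format(x$boundary, big.mark = ",")))
  cat("  C-terminal: "); print(x$c_terminal)
  cat("  N-terminal: "); print(x$n_terminal)
  invisible(x)
}

#' Read a viewpoint anchor set from YAML
#'
#' Expected keys: `gene`, `chrom`, `c_terminal: [start, end]`,
#' `n_terminal: [start, end]`, optional `background: [start, end]`.
#' Coordinates are 0-based half-open. The configuration shipped at
#' `system.file("extdata", "braf_anchors.yaml", package = "fusion4c")` holds
#' the BRAF anchors on GRCh38 chromosome 7.
#'
#' @param path YAML file path.
#' @return An `anchor_set`.
#' @export
read_anchor_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  bg <- if (!is.null(y$background)) gi(y$chrom, y$background[[1]], y$background[[2]])
  anchor_set(y$gene,
             c_terminal = gi(y$chrom, y$c_terminal[[1]], y$c_terminal[[2]]),
             n_terminal = gi(y$chrom, y$n_terminal[[1]], y$n_terminal[[2]]),
             background = bg)
}

# fine-bin membership of an interval (interval must be fine-bin aligned)
anchor_fine_bins <- function(bins, interval) {
  bs <- attr(bins, "bin_size")
  if (interval$start %% bs != 0 || interval$end %% bs != 0)
    stop_fmt("anchor [%s, %s) is not aligned to the %s bp fine grid",
             format(interval$start, big.mark = ","),
             format(interval$end, big.mark = ","), format(bs, big.mark = ","))
  bins_overlapping(bins, interval)
}

#' Extract a virtual 4C profile
#'
#' For every coarse bin (phased at the shared terminal boundary via the same
#' rule as [coarsen_anchored()]), sums the fine-bin contacts between that bin
#' and each of the three anchors, and normalizes the two terminal sums by the
#' full-gene background sum: `norm_c = raw_c / raw_bg`,
#' `norm_n = raw_n / raw_bg`. Because the terminals partition the background,
#' `raw_bg = raw_c + raw_n` and `norm_c + norm_n = 1` on every defined bin;
#' the ratio cancels the distance bias between a bin and the viewpoint. Bins
#' with no contact to the background are flagged missing (never 0/0), and
#' bins overlapping the background are flagged `self` and excluded from peak
#' calling.
#'
#' Raw counts are used by default: the normalization is itself a per-bin
#' ratio against the same anchor, which cancels per-bin biases, so balancing
#' is optional (`use_weights`).
#'
#' @param mat Fine-resolution [contact_matrix()] containing the anchor
#'   chromosome.
#' @param anchors An [anchor_set()] with fine-bin-aligned boundaries.
#' @param coarse_factor Integer; coarse width = factor x fine width
#'   (default 5: 10 kb -> 50 kb).
#' @param use_weights Sum balanced instead of raw counts.
#' @return A `v4c_profile`: data.frame with `chrom`, `start`, `end`, `bin`,
#'   `raw_c`, `raw_n`, `raw_bg`, `norm_c`, `norm_n`, `self`; attributes
#'   `gene`, `sample`, `bin_size`, `fine_bin_size`, `boundary`, `anchors`,
#'   `chrom_lengths`.
#' @export
extract_profile <- function(mat, anchors, coarse_factor = 5L, use_weights = FALSE) {
  stopifnot(inherits(anchors, "anchor_set"))
  fine_bins <- mat$bins
  fine <- attr(fine_bins, "bin_size")
  if (!anchors$background$chrom %in% fine_bins$chrom)
    stop_fmt("matrix does not contain anchor chromosome '%s'", anchors$background$chrom)
  memb_c <- anchor_fine_bins(fine_bins, anchors$c_terminal)
  memb_n <- anchor_fine_bins(fine_bins, anchors$n_terminal)
  memb_bg <- anchor_fine_bins(fine_bins, anchors$background)
  cl <- attr(fine_bins, "chrom_lengths")
  coarse <- bin_table(cl, fine * coarse_factor,
                      anchor_chrom = anchors$background$chrom,
                      anchor_pos = anchors$boundary)
  map <- locate_bins(coarse, fine_bins$chrom, fine_bins$start)
  e <- mat$entries
  v <- e$count
  if (use_weights) {
    if (is.null(mat$weights)) stop_fmt("use_weights = TRUE requires balancing weights")
    v <- v * mat$weights[e$bin1] * mat$weights[e$bin2]
    keep <- !is.na(v)
    e <- e[keep, , drop = FALSE]; v <- v[keep]
  }
  nco <- nrow(coarse)
  anchor_sum <- function(members) {
    s <- numeric(nco)
    in2 <- e$bin2 %in% members       # partner bin1 accumulates
    in1 <- e$bin1 %in% members & e$bin1 != e$bin2  # partner bin2 accumulates
    idx <- c(map[e$bin1[in2]], map[e$bin2[in1]])
    val <- c(v[in2], v[in1])
    if (length(idx) > 0L) {
      r <- rowsum(val, idx, reorder = TRUE)
      s[as.integer(rownames(r))] <- r[, 1L]
    }
    s
  }
  raw_c <- anchor_sum(memb_c)
  raw_n <- anchor_sum(memb_n)
  raw_bg <- anchor_sum(memb_bg)
  norm_c <- ifelse(raw_bg > 0, raw_c / raw_bg, NA_real_)
  norm_n <- ifelse(raw_bg > 0, raw_n / raw_bg, NA_real_)
  self <- coarse$chrom == anchors$background$chrom &
    coarse$start < anchors$background$end & coarse$end > anchors$background$start
  prof <- data.frame(chrom = coarse$chrom, start = coarse$start, end = coarse$end,
                     bin = coarse$bin, raw_c = raw_c, raw_n = raw_n,
                     raw_bg = raw_bg, norm_c = norm_c, norm_n = norm_n,
                     self = self, stringsAsFactors = FALSE)
  attr(prof, "gene") <- anchors$gene
  attr(prof, "sample") <- mat$sample
  attr(prof, "bin_size") <- fine * coarse_factor
  attr(prof, "fine_bin_size") <- fine
  attr(prof, "boundary") <- anchors$boundary
  attr(prof, "anchors") <- anchors
  attr(prof, "chrom_lengths") <- cl
  class(prof) <- c("v4c_profile", "data.frame")
  prof
}

#' Re-bin a virtual 4C profile to a coarser resolution
#'
#' Raw anchor sums are re-summed into larger bins (phased at the same
#' boundary, so the new edges nest exactly in the old ones) and the
#' normalized fractions recomputed from the re-binned raws. Re-binning raws
#' this way is identical to direct extraction at the coarser resolution.
#'
#' @param profile A `v4c_profile`.
#' @param factor Integer aggregation factor.
#' @return A `v4c_profile` at `factor` times the bin size.
#' @export
rebin_profile <- function(profile, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop_fmt("factor must be a positive integer")
  if (factor == 1L) return(profile)
  cl <- attr(profile, "chrom_lengths")
  anchors <- attr(profile, "anchors")
  newsize <- attr(profile, "bin_size") * factor
  coarse <- bin_table(cl, newsize, anchor_chrom = anchors$background$chrom,
                      anchor_pos = anchors$boundary)
  map <- locate_bins(coarse, profile$chrom, profile$start)
  agg <- function(x) {
    s <- numeric(nrow(coarse))
    r <- rowsum(x, map, reorder = TRUE)
    s[as.integer(rownames(r))] <- r[, 1L]
    s
  }
  raw_c <- agg(profile$raw_c); raw_n <- agg(profile$raw_n); raw_bg <- agg(profile$raw_bg)
  self <- coarse$chrom == anchors$background$chrom &
    coarse$start < anchors$background$end & coarse$end > anchors$background$start
  prof <- data.frame(chrom = coarse$chrom, start = coarse$start, end = coarse$end,
                     bin = coarse$bin, raw_c = raw_c, raw_n = raw_n, raw_bg = raw_bg,
                     norm_c = ifelse(raw_bg > 0, raw_c / raw_bg, NA_real_),
                     norm_n = ifelse(raw_bg > 0, raw_n / raw_bg, NA_real_),
                     self = self, stringsAsFactors = FALSE)
  for (a in c("gene", "sample", "fine_bin_size", "boundary", "anchors", "chrom_lengths"))
    attr(prof, a) <- attr(profile, a)
  attr(prof, "bin_size") <- newsize
  class(prof) <- c("v4c_profile", "data.frame")
  prof
}

#' Detect fusion-partner loci as sample-exclusive interaction peaks
#'
#' Formalizes the "exclusive peak" read-out: for each eligible bin, each
#' sample's normalized interaction fraction is converted to a leave-one-out
#' cohort z-score (mean and SD over the other samples at that bin). A
#' candidate is a bin where exactly one sample exceeds the z threshold with
#' an absolute excess of at least `min_effect` over the cohort mean; adjacent
#' candidate bins (gap <= `merge_gap` bins) are merged into loci ranked by
#' peak z. Bins overlapping the viewpoint background, or within
#' `exclusion_flank` of it on the anchor chromosome, are excluded (the
#' viewpoint's own neighborhood interacts strongly in every sample). The
#' absolute-effect requirement guards against the heavy tails of a z-score
#' estimated from a handful of cohort samples; with the default simulator a
#' planted fusion shifts the fraction by ~0.5 while count noise is ~0.02.
#'
#' @param profiles List of >= 2 `v4c_profile`s on a shared bin table.
#' @param terminal Which terminal's fraction to scan: `"c"` (kept) or `"n"`.
#' @param exclusion_flank bp excluded around the background anchor.
#' @param z_threshold Leave-one-out z threshold.
#' @param min_effect Minimum absolute excess over the cohort mean (norm units).
#' @param sd_floor Lower bound on the cohort SD.
#' @param merge_gap Candidate bins separated by <= this many bins are merged.
#' @return data.frame with one row per candidate locus: `sample`, `chrom`,
#'   `start`, `end`, `n_bins`, `peak_z`, `peak_delta`, `peak_start`
#'   (start of the peak bin). Zero rows when no sample has an exclusive peak.
#' @export
detect_partner_peaks <- function(profiles, terminal = c("c", "n"),
                                 exclusion_flank = 1e6, z_threshold = 4,
                                 min_effect = 0.15, sd_floor = 1e-3,
                                 merge_gap = 1L) {
  terminal <- match.arg(terminal)
  if (length(profiles) < 2L)
    stop_fmt("exclusivity is undefined for a cohort of %d profile(s)", length(profiles))
  p0 <- profiles[[1L]]
  for (p in profiles[-1L])
    if (!(nrow(p) == nrow(p0) && all(p$chrom == p0$chrom) && all(p$start == p0$start)))
      stop_fmt("profiles do not share a bin table")
  anchors <- attr(p0, "anchors")
  bg <- anchors$background
  excluded <- p0$self |
    (p0$chrom == bg$chrom & p0$start < bg$end + exclusion_flank &
       p0$end > bg$start - exclusion_flank)
  X <- vapply(profiles, function(p) p[[paste0("norm_", terminal)]], numeric(nrow(p0)))
  S <- ncol(X)
  samples <- vapply(seq_len(S), function(i)
    attr(profiles[[i]], "sample") %||% sprintf("sample_%d", i), "")
  samples[is.na(samples)] <- sprintf("sample_%d", which(is.na(samples)))
  Z <- matrix(NA_real_, nrow(X), S)
  D <- matrix(NA_real_, nrow(X), S)
  n_zero_var <- 0L
  for (s in seq_len(S)) {
    others <- X[, -s, drop = FALSE]
    n_ok <- rowSums(!is.na(others))
    m <- rowMeans(others, na.rm = TRUE)
    sdv <- apply(others, 1L, stats::sd, na.rm = TRUE)
    zero <- !is.na(sdv) & sdv == 0
    n_zero_var <- n_zero_var + sum(zero & !excluded & !is.na(X[, s]))
    sdv[zero] <- NA_real_                 # degenerate bins are skipped
    sdv <- pmax(sdv, sd_floor)
    ok <- !excluded & n_ok >= 2L & !is.na(X[, s]) & !is.na(sdv)
    D[ok, s] <- X[ok, s] - m[ok]
    Z[ok, s] <- D[ok, s] / sdv[ok]
  }
  if (n_zero_var > 0L)
    warn_fmt("%d bin/sample value(s) had zero cross-sample variance", n_zero_var)
  exceed <- !is.na(Z) & Z > z_threshold & D >= min_effect
  exclusive <- exceed & rowSums(exceed) == 1L
  out <- list()
  for (s in seq_len(S)) {
    cand <- which(exclusive[, s])
    if (length(cand) == 0L) next
    ch <- p0$chrom[cand]
    grp <- cumsum(c(TRUE, diff(cand) > merge_gap + 1L | ch[-1L] != ch[-length(ch)]))
    for (g in unique(grp)) {
      b <- cand[grp == g]
      pk <- b[which.max(Z[b, s])]
      out[[length(out) + 1L]] <- data.frame(
        sample = samples[s], chrom = p0$chrom[pk],
        start = min(p0$start[b]), end = max(p0$end[b]),
        n_bins = length(b), peak_z = max(Z[b, s]),
        peak_delta = D[pk, s], peak_start = p0$start[pk],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample = character(), chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(), peak_z = numeric(),
                      peak_delta = numeric(), peak_start = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(-res$peak_z), , drop = FALSE]
}

#' Per-sample, per-locus exclusivity report
#'
#' Mean normalized interaction of each sample with each queried locus (e.g.
#' the KIAA1549, PTPRZ1 or GNAI1 loci), at a coarser reporting resolution.
#' Profiles are re-binned on the fly by re-summing raw anchor counts.
#'
#' @param profiles List of `v4c_profile`s on a shared bin table.
#' @param loci Named list of [gi()] intervals.
#' @param resolution Reporting bin size in bp (default 500 kb); must be a
#'   multiple of the profile bin size.
#' @return data.frame with `sample`, `locus`, `chrom`, `norm_c`, `norm_n`,
#'   `n_bins`.
#' @export
exclusivity_report <- function(profiles, loci, resolution = 5e5) {
  bs <- attr(profiles[[1L]], "bin_size")
  if (resolution %% bs != 0)
    stop_fmt("reporting resolution must be a multiple of the %s bp profile bins",
             format(bs, big.mark = ","))
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    names(loci) <- vapply(loci, function(l) sprintf("%s:%s", l$chrom,
                                                    format(l$start, big.mark = ",")), "")
  rp <- lapply(profiles, rebin_profile, factor = resolution %/% bs)
  out <- list()
  for (i in seq_along(rp)) {
    p <- rp[[i]]
    sample <- attr(p, "sample") %||% sprintf("sample_%d", i)
    if (is.na(sample)) sample <- sprintf("sample_%d", i)
    for (nm in names(loci)) {
      l <- as_gi(loci[[nm]])
      ov <- p$chrom == l$chrom & p$start < l$end & p$end > l$start
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, locus = nm, chrom = l$chrom,
        norm_c = mean(p$norm_c[ov], na.rm = TRUE),
        norm_n = mean(p$norm_n[ov], na.rm = TRUE),
        n_bins = sum(ov), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a virtual 4C profile as multi-column TSV
#' @param profile A `v4c_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a virtual 4C profile
#'
#' Normalized interaction fraction with the chosen terminal along one
#' chromosome; the viewpoint background is shaded.
#'
#' @param x A `v4c_profile`.
#' @param chrom Chromosome to plot (default: the anchor chromosome).
#' @param terminal `"c"` or `"n"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.v4c_profile <- function(x, chrom = NULL, terminal = "c", ...) {
  anchors <- attr(x, "anchors")
  chrom <- chrom %||% anchors$background$chrom
  sub <- x[x$chrom == chrom, , drop = FALSE]
  y <- sub[[paste0("norm_", terminal)]]
  plot((sub$start + sub$end) / 2 / 1e6, y, type = "l",
       xlab = sprintf("%s position (Mb)", chrom),
       ylab = sprintf("fraction of gene contacts on %s-terminal", toupper(terminal)),
       ...)
  if (chrom == anchors$background$chrom)
    rect(anchors$background$start / 1e6, 0, anchors$background$end / 1e6, 1,
         col = grDevices::adjustcolor("grey", 0.4), border = NA)
  invisible(x)
}
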