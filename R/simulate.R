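#' Simulation configuration
#'
#' Parameters of the contact-map generator. Cis contacts follow a power-law
#' distance decay: the expected count of a derived-cis pair at separation `d`
#' bins is proportional to `(d + 1)^-decay_exponent`, multiplied by
#' `compartment_boost` when both bins carry the same planted compartment
#' label; trans pairs get a flat `trans_rate`. Expectations are scaled to the
#' configured sequencing depth and counts are Poisson-sampled per bin pair
#' (the standard shot-noise model), so finite depth and seeded determinism
#' come for free.
#'
#' @param bin_size Bin width in bp.
#' @param decay_exponent Power-law slope of cis decay (> 0; default 1, the
#'   canonical Hi-C value).
#' @param trans_rate Relative expected weight of a trans bin pair.
#' @param depth Total expected read-pair count (> 0).
#' @param compartment_labels Optional per-REFERENCE-bin `"A"`/`"B"` vector
#'   (checkerboard structure); see [checkerboard_labels()].
#' @param compartment_boost Within-type contact boost factor (>= 1).
#' @param seed Integer random seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(bin_size = 1e4, decay_exponent = 1, trans_rate = 0.01,
                              depth = 3e6, compartment_labels = NULL,
                              compartment_boost = 1, seed = 1L) {
  if (bin_size <= 0) stop_fmt("bin_size must be > 0")
  if (decay_exponent <= 0) stop_fmt("decay_exponent must be > 0")
  if (!is.finite(depth) || depth <= 0) stop_fmt("depth must be > 0")
  if (compartment_boost < 1) stop_fmt("compartment boost factor must be >= 1")
  structure(list(bin_size = bin_size, decay_exponent = decay_exponent,
                 trans_rate = trans_rate, depth = depth,
                 compartment_labels = compartment_labels,
                 compartment_boost = compartment_boost, seed = as.integer(seed)),
            class = "sim_config")
}

#' Alternating A/B block labels
#' @param n_bins Number of bins.
#' @param block_bins Bins per compartment block.
#' @param first Label of the first block.
#' @return Character vector of `"A"`/`"B"`.
#' @export
checkerboard_labels <- function(n_bins, block_bins = 10L, first = "A") {
  blocks <- (seq_len(n_bins) - 1L) %/% block_bins
  second <- setdiff(c("A", "B"), first)
  ifelse(blocks %% 2L == 0L, first, second)
}

# per-pair expected weights (before depth scaling) over derived bins.
# returns list(i, j, w) for the upper triangle (i <= j), derived indices.
derived_expectation <- function(genome, config) {
  db <- genome$bins_derived
  n <- nrow(db)
  chrom_id <- as.integer(factor(db$chrom, levels = unique(db$chrom)))
  pos <- sequence(tabulate(chrom_id))  # index within chromosome
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  same <- chrom_id[i] == chrom_id[j]
  w <- numeric(length(i))
  d <- abs(pos[j] - pos[i])
  w[same] <- (d[same] + 1)^(-config$decay_exponent)
  w[!same] <- config$trans_rate
  if (!is.null(config$compartment_labels)) {
    lab <- config$compartment_labels[lift_to_reference(genome, db$bin)]
    boost <- !is.na(lab[i]) & !is.na(lab[j]) & lab[i] == lab[j]
    w[boost] <- w[boost] * config$compartment_boost
  }
  list(i = i, j = j, w = w)
}

#' Expected reference-coordinate contact map of a simulation
#'
#' The per-pair Poisson means of [simulate_contact_matrix()], mapped from
#' derived to reference bins (duplicated reference bins receive the summed
#' contributions of all derived copies). Useful for variance checks and as a
#' direct view of where a planted rearrangement adds ectopic signal.
#'
#' @param genome A `derived_genome`.
#' @param config A [simulation_config()].
#' @return A [contact_matrix()] on the reference bins whose `count` column
#'   holds expected (non-integer) counts.
#' @export
expected_reference_contacts <- function(genome, config) {
  ex <- derived_expectation(genome, config)
  lam <- ex$w * config$depth / sum(ex$w)
  r1 <- lift_to_reference(genome, ex$i)
  r2 <- lift_to_reference(genome, ex$j)
  contact_matrix(genome$bins_reference,
                 data.frame(bin1 = r1, bin2 = r2, count = lam),
                 sample = "expected")
}

#' Simulate a Hi-C contact matrix from a derived genome
#'
#' Contacts are generated in DERIVED coordinates under the
#' [simulation_config()] kernel, Poisson-sampled at the configured depth with
#' the configured seed, then mapped back through the lift-over to REFERENCE
#' bins and symmetrized. Duplicated reference bins receive summed
#' contributions from all derived copies — exactly what a reference-aligned
#' Hi-C map of a duplicated region shows, and the origin of the ectopic
#' contact signature at rearrangement junctions.
#'
#' @param genome A `derived_genome` (from [build_derived_genome()]).
#' @param config A [simulation_config()]; bin sizes must agree.
#' @return list with `matrix` (a [contact_matrix()] on the reference bins),
#'   `truth` (the planted junctions as an [sv_calls()] table) and
#'   `compartment_labels`.
#' @export
simulate_contact_matrix <- function(genome, config) {
  if (config$bin_size != genome$bin_size)
    stop_fmt("config bin_size (%s) does not match genome bin_size (%s)",
             config$bin_size, genome$bin_size)
  if (!is.null(config$compartment_labels) &&
      length(config$compartment_labels) != nrow(genome$bins_reference))
    stop_fmt("compartment_labels must have one label per reference bin (%d)",
             nrow(genome$bins_reference))
  ex <- derived_expectation(genome, config)
  lam <- ex$w * config$depth / sum(ex$w)
  counts <- with_seed(config$seed, stats::rpois(length(lam), lam))
  nz <- counts > 0L
  r1 <- lift_to_reference(genome, ex$i[nz])
  r2 <- lift_to_reference(genome, ex$j[nz])
  mat <- contact_matrix(genome$bins_reference,
                        data.frame(bin1 = r1, bin2 = r2, count = counts[nz]))
  list(matrix = mat, truth = genome$breakpoints,
       compartment_labels = config$compartment_labels)
}

#' Simulate multi-caller SV call sets with known ground truth
#'
#' Each true event is emitted by each caller with probability `1 - dropout`;
#' both breakpoints are independently jittered by rounded Gaussian noise of
#' scale `jitter_sd` and clamped to the chromosome. `fp_per_caller` unrelated
#' random cis calls are added per caller. Ground-truth labels are retained in
#' the `truth_id` column (`NA` for false positives).
#'
#' @param truth An [sv_calls()]-like table of true junctions (e.g. the
#'   `truth` element of [simulate_contact_matrix()], or any table with
#'   `chrom1`, `pos1`, `chrom2`, `pos2`, `sv_type`).
#' @param n_callers Number of simulated callers (>= 1).
#' @param jitter_sd Breakpoint jitter SD in bp (>= 0).
#' @param dropout Per-caller probability of missing a true event.
#' @param fp_per_caller False positives added per caller.
#' @param chrom_lengths Named lengths used to place false positives and clamp
#'   jittered breakpoints.
#' @param seed Integer seed.
#' @return Named list (`caller_1`, ...) of [sv_calls()] tables.
#' @export
simulate_callsets <- function(truth, n_callers = 4L, jitter_sd = 300,
                              dropout = 0, fp_per_caller = 0L,
                              chrom_lengths = NULL, seed = 1L) {
  if (n_callers < 1L) stop_fmt("n_callers must be >= 1")
  if (jitter_sd < 0) stop_fmt("jitter_sd must be >= 0")
  if (dropout < 0 || dropout > 1) stop_fmt("dropout must be a probability")
  if (fp_per_caller > 0L && is.null(chrom_lengths))
    stop_fmt("chrom_lengths required to place false positives")
  truth <- as.data.frame(truth)
  nt <- nrow(truth)
  clamp <- function(pos, chrom) {
    if (is.null(chrom_lengths)) return(pmax(pos, 0))
    pmin(pmax(pos, 0), as_chrom_lengths(chrom_lengths)[chrom] - 1)
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_callers), function(k) {
      detected <- if (nt > 0L) stats::runif(nt) >= dropout else logical()
      tp <- if (any(detected)) {
        idx <- which(detected)
        sv_calls(truth$chrom1[idx],
                 clamp(truth$pos1[idx] + round(stats::rnorm(length(idx), 0, jitter_sd)),
                       truth$chrom1[idx]),
                 truth$chrom2[idx],
                 clamp(truth$pos2[idx] + round(stats::rnorm(length(idx), 0, jitter_sd)),
                       truth$chrom2[idx]),
                 sv_type = truth$sv_type[idx],
                 caller = sprintf("caller_%d", k),
                 truth_id = if ("truth_id" %in% names(truth) && !all(is.na(truth$truth_id)))
                   truth$truth_id[idx] else idx)
      } else empty_sv_calls()
      fp <- if (fp_per_caller > 0L) {
        cl <- as_chrom_lengths(chrom_lengths)
        ch <- sample(names(cl), fp_per_caller, replace = TRUE,
                     prob = cl / sum(cl))
        size <- floor(stats::runif(fp_per_caller, 1e3, pmin(1e6, cl[ch] / 2)))
        maxp <- pmax(cl[ch] - size - 1, 2)
        p1 <- floor(stats::runif(fp_per_caller) * (maxp - 1)) + 1
        sv_calls(ch, p1, ch, pmin(p1 + size, cl[ch] - 1),
                 sv_type = sample(c("DEL", "DUP", "INV"), fp_per_caller, replace = TRUE),
                 caller = sprintf("caller_%d", k))
      } else empty_sv_calls()
      rbind(tp, fp)
    })
    names(out) <- sprintf("caller_%d", seq_len(n_callers))
    out
  })
}
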