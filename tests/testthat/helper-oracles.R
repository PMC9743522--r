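# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's sparse code paths: everything here is dense double
# loops over full symmetric matrices.

# full dense symmetric matrix from a contact_matrix
dense_matrix <- function(mat) {
  n <- nrow(mat$bins)
  M <- matrix(0, n, n)
  e <- mat$entries
  for (k in seq_len(nrow(e))) {
    M[e$bin1[k], e$bin2[k]] <- M[e$bin1[k], e$bin2[k]] + e$count[k]
    if (e$bin1[k] != e$bin2[k])
      M[e$bin2[k], e$bin1[k]] <- M[e$bin2[k], e$bin1[k]] + e$count[k]
  }
  M
}

# exhaustive virtual-4C anchor sums: for each coarse bin, loop over its fine
# bins f and all anchor fine bins a, accumulating M_sym[f, a]
oracle_v4c_sums <- function(mat, coarse_bins, anchor_interval) {
  M <- dense_matrix(mat)
  fine <- mat$bins
  a_bins <- fine$bin[fine$chrom == anchor_interval$chrom &
                     fine$start >= anchor_interval$start &
                     fine$end <= anchor_interval$end]
  out <- numeric(nrow(coarse_bins))
  for (cb in seq_len(nrow(coarse_bins))) {
    fb <- fine$bin[fine$chrom == coarse_bins$chrom[cb] &
                   fine$start >= coarse_bins$start[cb] &
                   fine$start < coarse_bins$end[cb]]
    s <- 0
    for (f in fb) for (a in a_bins) s <- s + M[f, a]
    out[cb] <- s
  }
  out
}

# brute-force expected reference-coordinate contact map: enumerate every
# derived bin pair, compute the kernel weight, scale to depth, and add it to
# the reference pair it lifts to
oracle_expected_reference <- function(genome, config) {
  db <- genome$bins_derived
  n <- nrow(db)
  lift <- genome$liftover$ref_bin[order(genome$liftover$dbin)]
  lab <- if (!is.null(config$compartment_labels))
    config$compartment_labels[lift] else NULL
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    if (db$chrom[i] == db$chrom[j]) {
      d <- sum(db$chrom == db$chrom[i] & db$start > min(db$start[c(i, j)]) &
               db$start <= max(db$start[c(i, j)]))
      w <- (d + 1)^(-config$decay_exponent)
    } else w <- config$trans_rate
    if (!is.null(lab) && !is.na(lab[i]) && !is.na(lab[j]) && lab[i] == lab[j])
      w <- w * config$compartment_boost
    W[i, j] <- w
  }
  scale <- config$depth / sum(W[upper.tri(W, diag = TRUE)])
  nr <- nrow(genome$bins_reference)
  E <- matrix(0, nr, nr)
  for (i in 1:n) for (j in i:n) {
    r1 <- min(lift[i], lift[j]); r2 <- max(lift[i], lift[j])
    E[r1, r2] <- E[r1, r2] + W[i, j] * scale
  }
  E
}

# O(n^2) pairwise double-breakpoint clustering with BFS components
oracle_match_components <- function(calls, tolerance) {
  n <- nrow(calls)
  if (n == 0L) return(integer())
  adj <- outer(calls$chrom1, calls$chrom1, "==") &
    outer(calls$chrom2, calls$chrom2, "==") &
    abs(outer(calls$pos1, calls$pos1, "-")) <= tolerance &
    abs(outer(calls$pos2, calls$pos2, "-")) <= tolerance
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in 1:n) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# partition of call ids induced by a consensus table (set of sets)
consensus_partition <- function(consensus) {
  sets <- lapply(consensus$members, function(m) sort(m))
  sets[order(vapply(sets, `[`, 0L, 1L))]
}

partition_from_membership <- function(membership) {
  sets <- lapply(split(seq_along(membership), membership), sort)
  unname(sets[order(vapply(sets, `[`, 0L, 1L))])
}

# random SV callsets for oracle-equivalence fuzzing
random_callsets <- function(n_calls, n_callers = 4L, seed = 1L) {
  set.seed(seed)
  per <- as.integer(table(factor(sample.int(n_callers, n_calls, replace = TRUE),
                                 levels = seq_len(n_callers))))
  chroms <- c("chr1", "chr2", "chr7")
  out <- lapply(seq_len(n_callers), function(k) {
    m <- per[k]
    if (m == 0L) return(fusion4c:::empty_sv_calls())
    c1 <- sample(chroms, m, replace = TRUE)
    c2 <- ifelse(runif(m) < 0.8, c1, sample(chroms, m, replace = TRUE))
    # cluster positions on a coarse lattice so collisions/chains happen
    p1 <- sample.int(40L, m, replace = TRUE) * 2500 +
      sample(c(0, 400, 900, 1000, 1100), m, replace = TRUE)
    p2 <- sample.int(40L, m, replace = TRUE) * 2500 +
      sample(c(0, 400, 900, 1000, 1100), m, replace = TRUE)
    sv_calls(c1, p1, c2, p2, sv_type = sample(c("DEL", "DUP", "BND"), m, TRUE),
             caller = sprintf("caller_%d", k))
  })
  names(out) <- sprintf("caller_%d", seq_len(n_callers))
  out
}

# tiny deterministic matrix following an exact power-law decay (no noise)
exact_decay_matrix <- function(n_bins = 40L, bin_size = 1e4, alpha = 1) {
  bins <- bin_table(c(chrT = n_bins * bin_size), bin_size)
  idx <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE), arr.ind = TRUE)
  entries <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2],
                        count = (abs(idx[, 2] - idx[, 1]) + 1)^(-alpha) * 1000)
  contact_matrix(bins, entries, sample = "decay")
}
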