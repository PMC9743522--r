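# balanced matrix with a planted checkerboard on a single chromosome
sim_compartment_matrix <- function(n_bins = 200L, block_bins = 20L, boost = 1.5,
                                   depth = 1e6, seed = 1L, bin_size = 5e4) {
  gen <- build_derived_genome(stats::setNames(n_bins * bin_size, "chrC"),
                              list(), bin_size)
  labels <- checkerboard_labels(n_bins, block_bins)
  sim <- simulate_contact_matrix(gen, simulation_config(
    bin_size = bin_size, depth = depth, trans_rate = 0,
    compartment_labels = labels, compartment_boost = boost, seed = seed))
  list(matrix = set_weights(sim$matrix, balance(sim$matrix)), labels = labels)
}

test_that("a two-block matrix is split with opposite signs, membership exact", {
  # 10 + 10 bins, strong within-block enrichment
  n <- 20L
  bins <- bin_table(c(chrC = n * 5e4), 5e4)
  block <- rep(c(1, 2), each = 10)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  base <- (abs(idx[, 2] - idx[, 1]) + 1)^-1 * 100
  same <- block[idx[, 1]] == block[idx[, 2]]
  e <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2],
                  count = base * ifelse(same, 2, 0.5))
  m <- set_weights(contact_matrix(bins, e), rep(1, n))
  orient <- ifelse(block == 1, 1, -1)
  tr <- compartment_score(m, "chrC", orient, min_bins = 10L)
  expect_true(all(tr$score[block == 1] > 0))
  expect_true(all(tr$score[block == 2] < 0))
  expect_equal(tr$label, ifelse(block == 1, "A", "B"))
})

test_that("negating the orientation track flips scores and labels", {
  sm <- sim_compartment_matrix(n_bins = 100L, seed = 5)
  orient <- a_density_track(sm$labels)
  t1 <- compartment_score(sm$matrix, "chrC", orient)
  t2 <- compartment_score(sm$matrix, "chrC", -orient)
  expect_equal(t2$score, -t1$score)
  swapped <- ifelse(t1$label == "A", "B", ifelse(t1$label == "B", "A", t1$label))
  expect_equal(t2$label, swapped)
  # sign convention is total: non-negative correlation with the track
  ok <- !is.na(t1$score)
  expect_gte(cor(t1$score[ok], orient[ok]), 0)
})

test_that("scores match a dense brute-force eigendecomposition", {
  sm <- sim_compartment_matrix(n_bins = 150L, seed = 9)
  tr <- compartment_score(sm$matrix, "chrC", a_density_track(sm$labels))
  # independent dense recomputation from the raw entries: balanced matrix,
  # expected per separation over unmasked pairs, O/E, Pearson, eigen
  m <- sm$matrix
  M <- dense_matrix(m)
  w <- m$weights
  n <- nrow(M)
  B <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n)
    if (!is.na(w[i]) && !is.na(w[j])) B[i, j] <- M[i, j] * w[i] * w[j]
  exp_by_sep <- numeric(n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in 1:(n - d)) if (!is.na(B[i, i + d])) vals <- c(vals, B[i, i + d])
    exp_by_sep[d + 1] <- if (length(vals) > 0) mean(vals) else NA
  }
  OE <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    ed <- exp_by_sep[abs(i - j) + 1]
    if (!is.na(B[i, j]) && !is.na(ed) && ed > 0) OE[i, j] <- B[i, j] / ed
  }
  sub <- which(!is.na(w))
  C <- cor(OE[sub, sub], use = "pairwise.complete.obs")
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1] * sqrt(eg$values[1])
  ot <- a_density_track(sm$labels)[sub]
  if (cor(v, ot) < 0) v <- -v
  expect_equal(tr$score[!is.na(tr$score)], v, tolerance = 1e-8)
  expect_equal(attr(tr, "eigen_index"), 1L)
})

test_that("planted checkerboard labels are recovered at >= 95% concordance", {
  sm <- sim_compartment_matrix(n_bins = 200L, block_bins = 20L, boost = 1.5,
                               depth = 1e6, seed = 41)
  tr <- compartment_score(sm$matrix, "chrC", a_density_track(sm$labels))
  ok <- !is.na(tr$score)
  expect_gte(mean(tr$label[ok] == sm$labels[ok]), 0.95)
})

test_that("compartment scores are invariant to a global count rescaling", {
  sm <- sim_compartment_matrix(n_bins = 100L, seed = 3)
  m2 <- sm$matrix
  m2$entries$count <- m2$entries$count * 7
  t1 <- compartment_score(sm$matrix, "chrC", a_density_track(sm$labels))
  t2 <- compartment_score(m2, "chrC", a_density_track(sm$labels))
  expect_equal(t1$score, t2$score, tolerance = 1e-9)
})

test_that("degenerate chromosomes raise a named error", {
  n <- 30L
  bins <- bin_table(c(chrD = n * 5e4), 5e4)
  # uniform matrix: correlation undefined (constant rows)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  m <- set_weights(contact_matrix(bins, data.frame(bin1 = idx[, 1],
                                                   bin2 = idx[, 2], count = 5)),
                   rep(1, n))
  expect_error(compartment_score(m, "chrD", rep(1, n)), "chrD")
})

test_that("track self-comparison and negation hit the correlation bounds", {
  sm <- sim_compartment_matrix(n_bins = 100L, seed = 13)
  tr <- compartment_score(sm$matrix, "chrC", a_density_track(sm$labels))
  neg <- tr; neg$score <- -neg$score
  attr(neg, "sample") <- "neg"
  attr(tr, "sample") <- "pos"
  sim <- compare_tracks(list(tr, tr, neg))
  expect_equal(unname(sim$correlation[1, 2]), 1)
  expect_equal(unname(sim$correlation[1, 3]), -1)
  expect_equal(diag(sim$correlation), c(pos = 1, pos = 1, neg = 1))
})

test_that("samples from two compartment profiles form two clean clusters", {
  tracks <- list()
  for (i in 1:3) {
    sm <- sim_compartment_matrix(n_bins = 120L, block_bins = 20L, seed = 100 + i)
    tracks[[i]] <- compartment_score(sm$matrix, "chrC", a_density_track(sm$labels))
    attr(tracks[[i]], "sample") <- sprintf("P1_%d", i)
  }
  for (i in 1:3) {
    gen <- build_derived_genome(c(chrC = 120 * 5e4), list(), 5e4)
    labels2 <- checkerboard_labels(120L, 20L, first = "B")  # phase-shifted profile
    sim <- simulate_contact_matrix(gen, simulation_config(
      bin_size = 5e4, depth = 1e6, trans_rate = 0,
      compartment_labels = labels2, compartment_boost = 1.5, seed = 200 + i))
    m <- set_weights(sim$matrix, balance(sim$matrix))
    tracks[[3 + i]] <- compartment_score(m, "chrC", a_density_track(labels2))
    attr(tracks[[3 + i]], "sample") <- sprintf("P2_%d", i)
  }
  sim <- compare_tracks(tracks)
  grp <- cutree(sim$linkage, k = 2)
  expect_equal(length(unique(grp[1:3])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
  expect_true(grp[1] != grp[4])
})

test_that("compartment_at summarizes overlapping bins and handles empty overlap", {
  sm <- sim_compartment_matrix(n_bins = 100L, block_bins = 20L, seed = 6)
  tr <- compartment_score(sm$matrix, "chrC", a_density_track(sm$labels))
  # first block is A: 20 bins x 50 kb
  at <- compartment_at(tr, gi("chrC", 0, 1e6))
  expect_equal(at$label, "A")
  expect_gt(at$mean_score, 0)
  at2 <- compartment_at(tr, gi("chrC", 1e6, 2e6))
  expect_equal(at2$label, "B")
  masked <- which(is.na(tr$score))
  if (length(masked) > 0) {
    iv <- gi("chrC", tr$start[masked[1]], tr$end[masked[1]])
    expect_equal(compartment_at(tr, iv)$label, "unassigned")
  }
})
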