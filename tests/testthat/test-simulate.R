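test_that("the same seed and config reproduce a bit-identical matrix", {
  gen <- build_derived_genome(c(chrA = 5e5, chrB = 2e5), list(), 1e4)
  cfg <- simulation_config(depth = 1e5, seed = 77)
  a <- simulate_contact_matrix(gen, cfg)
  b <- simulate_contact_matrix(gen, cfg)
  expect_identical(a$matrix$entries, b$matrix$entries)
  c <- simulate_contact_matrix(gen, simulation_config(depth = 1e5, seed = 78))
  expect_false(identical(a$matrix$entries, c$matrix$entries))
})

test_that("the decay kernel has the stated closed form: E[sep 1]/E[sep 3] = 2", {
  gen <- build_derived_genome(c(chrA = 5e5), list(), 1e4)
  cfg <- simulation_config(depth = 1e6, decay_exponent = 1, seed = 1)
  E <- dense_matrix(expected_reference_contacts(gen, cfg))
  # ratio of (d+1) factors: (1+1)^-1 / (3+1)^-1 = 2
  expect_equal(E[1, 2] / E[1, 4], 2)
  expect_equal(E[10, 11] / E[10, 13], 2)
})

test_that("zero or negative depth is rejected", {
  expect_error(simulation_config(depth = 0), "depth")
  expect_error(simulation_config(decay_exponent = 0), "decay")
  expect_error(simulation_config(compartment_boost = 0.5), "boost")
})

test_that("total counts concentrate on the configured depth (mass conservation)", {
  gen <- build_derived_genome(c(chrA = 3e5), list(), 1e4)
  depth <- 5e4
  totals <- vapply(1:100, function(s) {
    total_count(simulate_contact_matrix(
      gen, simulation_config(depth = depth, seed = s))$matrix)
  }, 0)
  # Poisson: SE of the mean of 100 totals is sqrt(depth/100)
  se <- sqrt(depth / 100)
  expect_lt(abs(mean(totals) - depth), 5 * se)
})

test_that("event-free expected counts are non-increasing in separation", {
  gen <- build_derived_genome(c(chrA = 6e5), list(), 1e4)
  cfg <- simulation_config(depth = 1e6, decay_exponent = 1.2, seed = 1)
  E <- dense_matrix(expected_reference_contacts(gen, cfg))
  n <- nrow(E)
  mean_by_sep <- vapply(0:(n - 1), function(d)
    mean(E[cbind(seq_len(n - d), seq_len(n - d) + d)]), 0)
  expect_true(all(diff(mean_by_sep) <= 1e-12))
})

test_that("expected reference map equals the brute-force enumeration oracle", {
  ev <- sv_event("tandem_duplication", "chrA", 1e5, 2.5e5)
  gen <- build_derived_genome(c(chrA = 5e5, chrB = 2e5), list(ev), 2.5e4)
  cfg <- simulation_config(bin_size = 2.5e4, depth = 1e5, trans_rate = 0.02,
                           compartment_labels = checkerboard_labels(28, 4),
                           compartment_boost = 1.4, seed = 1)
  E_pkg <- dense_matrix(expected_reference_contacts(gen, cfg))
  E_oracle <- oracle_expected_reference(gen, cfg)
  E_oracle <- E_oracle + t(E_oracle) - diag(diag(E_oracle))
  expect_equal(E_pkg, E_oracle, tolerance = 1e-12)
})

test_that("a planted tandem duplication adds ectopic signal at its junction", {
  bin <- 2.5e4
  ref <- c(chrA = 5e5)
  ev <- sv_event("tandem_duplication", "chrA", 1.5e5, 3e5)
  cfg <- simulation_config(bin_size = bin, depth = 1e5, seed = 1)
  g0 <- build_derived_genome(ref, list(), bin)
  g1 <- build_derived_genome(ref, list(ev), bin)
  E0 <- oracle_expected_reference(g0, cfg)
  E1 <- oracle_expected_reference(g1, cfg)
  # bins flanking the two duplication breakpoints: junction joins ref 3e5 -> 1.5e5
  left <- locate_bins(g0$bins_reference, "chrA", 1.5e5)      # first bin inside dup
  right <- locate_bins(g0$bins_reference, "chrA", 3e5 - bin) # last bin inside dup
  expect_gt(E1[left, right], E0[left, right])
  # strictly increased relative to a matched far-away pair
  far1 <- locate_bins(g0$bins_reference, "chrA", 0)
  far2 <- locate_bins(g0$bins_reference, "chrA", 4.5e5)
  expect_lt(E1[far1, far2] / E0[far1, far2], E1[left, right] / E0[left, right])
})

test_that("simulated callsets honor jitter, dropout and ground-truth labels", {
  truth <- sv_calls(c("chrA", "chrA"), c(1e5, 4e5), c("chrA", "chrB"),
                    c(2e5, 1e5), sv_type = c("DUP", "TRA"))
  cs <- simulate_callsets(truth, n_callers = 3L, jitter_sd = 0, dropout = 0,
                          fp_per_caller = 0L, seed = 5)
  expect_length(cs, 3L)
  for (k in cs) {
    expect_equal(nrow(k), 2L)
    expect_equal(k$pos1, truth$pos1)
    expect_equal(k$pos2, truth$pos2)
    expect_equal(k$truth_id, 1:2)
  }
  cs2 <- simulate_callsets(truth, n_callers = 3L, dropout = 1, seed = 5)
  expect_true(all(vapply(cs2, nrow, 0L) == 0L))
  cs3 <- simulate_callsets(truth, n_callers = 2L, jitter_sd = 300,
                           fp_per_caller = 4L, seed = 5,
                           chrom_lengths = c(chrA = 5e6, chrB = 5e6))
  expect_true(all(vapply(cs3, function(x) sum(is.na(x$truth_id)), 0L) == 4L))
  expect_false(all(cs3$caller_1$pos1[!is.na(cs3$caller_1$truth_id)] == truth$pos1))
})

test_that("jittered-callset consensus recovery matches a regenerated recount", {
  set.seed(404)
  truth <- sv_calls(rep("chrA", 10), seq(1e6, 10e6, by = 1e6), rep("chrA", 10),
                    seq(1e6, 10e6, by = 1e6) + 5e4, sv_type = "DUP")
  cs <- simulate_callsets(truth, n_callers = 4L, jitter_sd = 300, dropout = 0.3,
                          seed = 99, chrom_lengths = c(chrA = 2e7))
  cons <- match_calls(cs, tolerance = 1000)
  recovered <- sum(!is.na(cons$truth_id) & cons$n_callers >= 2)
  # brute-force recount of the same generative process: how many truths did
  # at least two callers emit?
  emitted <- table(unlist(lapply(cs, function(k) unique(k$truth_id))))
  expect_equal(recovered, sum(emitted >= 2))
})
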