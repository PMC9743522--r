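make_test_anchors <- function() {
  anchor_set("GENE",
             c_terminal = gi("chrA", 2.0e5, 2.4e5),
             n_terminal = gi("chrA", 2.4e5, 3.0e5))
}

test_that("anchors must partition the background exactly", {
  expect_error(anchor_set("G", gi("chrA", 0, 1e5), gi("chrA", 2e5, 3e5)),
               "adjacent")
  expect_error(anchor_set("G", gi("chrA", 0, 1e5), gi("chrB", 1e5, 2e5)),
               "one chromosome")
  expect_error(anchor_set("G", gi("chrA", 0, 1e5), gi("chrA", 1e5, 2e5),
                          background = gi("chrA", 0, 3e5)),
               "union")
  a <- anchor_set("G", gi("chrA", 1e5, 2e5), gi("chrA", 0, 1e5))
  expect_equal(a$boundary, 1e5)   # N before C also allowed
})

test_that("normalized fractions split the background sum exactly (30/70 case)", {
  # two fine bins of signal into a coarse bin: 30 to C, 70 to N
  bins <- bin_table(c(chrA = 5e5), 1e4)
  cbin <- locate_bins(bins, "chrA", 2.0e5)  # inside C anchor
  nbin <- locate_bins(bins, "chrA", 2.5e5)  # inside N anchor
  far <- locate_bins(bins, "chrA", 4.0e5)
  m <- contact_matrix(bins, data.frame(bin1 = c(cbin, nbin), bin2 = c(far, far),
                                       count = c(30, 70)))
  p <- extract_profile(m, make_test_anchors(), coarse_factor = 5L)
  row <- p[p$start <= 4.0e5 & p$end > 4.0e5 & p$chrom == "chrA", ]
  expect_equal(row$raw_c, 30)
  expect_equal(row$raw_n, 70)
  expect_equal(row$raw_bg, 100)
  expect_equal(row$norm_c, 0.3)
  expect_equal(row$norm_n, 0.7)
})

test_that("bins with no background contact are flagged missing, not 0/0", {
  bins <- bin_table(c(chrA = 5e5), 1e4)
  m <- contact_matrix(bins, data.frame(bin1 = 1L, bin2 = 2L, count = 5))
  p <- extract_profile(m, make_test_anchors(), coarse_factor = 5L)
  expect_true(all(is.na(p$norm_c[p$raw_bg == 0])))
  expect_true(all(is.na(p$norm_n[p$raw_bg == 0])))
})

test_that("misaligned anchors are rejected", {
  bins <- bin_table(c(chrA = 5e5), 1e4)
  m <- contact_matrix(bins, data.frame(bin1 = 1L, bin2 = 2L, count = 5))
  bad <- anchor_set("G", gi("chrA", 2.05e5, 2.4e5), gi("chrA", 2.4e5, 3.0e5))
  expect_error(extract_profile(m, bad), "aligned")
})

test_that("profile raw sums equal the exhaustive fine-pair double loop", {
  ev <- sv_event("tandem_duplication", "chrA", 1e5, 2.4e5)
  gen <- build_derived_genome(c(chrA = 5e5, chrB = 2e5), list(ev), 1e4)
  sim <- simulate_contact_matrix(gen, simulation_config(depth = 2e5, seed = 13))
  anchors <- make_test_anchors()
  p <- extract_profile(sim$matrix, anchors, coarse_factor = 5L)
  coarse <- data.frame(chrom = p$chrom, start = p$start, end = p$end)
  expect_equal(p$raw_c, oracle_v4c_sums(sim$matrix, coarse, anchors$c_terminal))
  expect_equal(p$raw_n, oracle_v4c_sums(sim$matrix, coarse, anchors$n_terminal))
  expect_equal(p$raw_bg, oracle_v4c_sums(sim$matrix, coarse, anchors$background))
})

test_that("partition identity holds on every defined bin of simulated cohorts", {
  co <- simulate_cohort(n_samples = 3L, depth = 5e5, seed = 21)
  for (s in co$samples) {
    p <- extract_profile(s$matrix, co$anchors, 5L)
    ok <- !is.na(p$norm_c)
    expect_true(any(ok))
    expect_lt(max(abs(p$norm_c[ok] + p$norm_n[ok] - 1)), 1e-12)
    expect_true(all(p$norm_c[ok] >= 0 & p$norm_c[ok] <= 1))
    expect_lt(max(abs(p$raw_bg - (p$raw_c + p$raw_n))), 1e-9)
  }
})

test_that("re-binning raw sums equals direct extraction at the coarser size", {
  co <- simulate_cohort(n_samples = 1L, fusion_sample = 1L, depth = 1e6, seed = 8)
  m <- co$samples[[1]]$matrix
  p50 <- extract_profile(m, co$anchors, 5L)       # 50 kb
  p500_direct <- extract_profile(m, co$anchors, 50L)  # 500 kb
  p500_rebin <- rebin_profile(p50, 10L)
  expect_equal(p500_rebin$raw_c, p500_direct$raw_c)
  expect_equal(p500_rebin$raw_n, p500_direct$raw_n)
  expect_equal(p500_rebin$norm_c, p500_direct$norm_c)
  expect_equal(p500_rebin$start, p500_direct$start)
})

test_that("identical profiles across a cohort yield no exclusive candidates", {
  co <- simulate_cohort(n_samples = 1L, fusion_sample = NULL, depth = 5e5, seed = 3)
  p <- extract_profile(co$samples[[1]]$matrix, co$anchors, 5L)
  profs <- list(p, p, p, p)
  expect_warning(pk <- detect_partner_peaks(profs), "zero cross-sample variance")
  expect_equal(nrow(pk), 0L)
  expect_error(detect_partner_peaks(list(p)), "cohort")
})

test_that("a planted fusion is the unique exclusive locus; controls are clean", {
  co <- simulate_cohort(n_samples = 6L, fusion_sample = 2L, seed = 314)
  profs <- lapply(co$samples, function(s) extract_profile(s$matrix, co$anchors, 5L))
  pk <- detect_partner_peaks(profs)
  expect_true(all(pk$sample == "sample_02"))
  pb <- co$partner_breakpoint
  expect_true(any(pk$chrom == pb$chrom & pk$start < pb$end & pk$end > pb$start))
  # negative control: drop the fusion sample and rerun
  pk0 <- detect_partner_peaks(profs[-2])
  expect_equal(nrow(pk0), 0L)
})

test_that("the exclusivity report ranks the fusion sample top at the partner locus", {
  co <- simulate_cohort(n_samples = 4L, fusion_sample = 1L, seed = 99)
  profs <- lapply(co$samples, function(s) extract_profile(s$matrix, co$anchors, 5L))
  pb <- co$partner_breakpoint
  rep <- exclusivity_report(profs, list(partner = gi(pb$chrom, pb$start, pb$start + 5e5)),
                            resolution = 5e5)
  vals <- rep$norm_c[rep$locus == "partner"]
  expect_equal(which.max(vals), 1L)
  # a locus equal to a single report bin returns that bin's norm
  p500 <- rebin_profile(profs[[1]], 10L)
  row <- p500[which(!is.na(p500$norm_c) & !p500$self)[1], ]
  rep1 <- exclusivity_report(profs[1], list(one = gi(row$chrom, row$start, row$end)))
  expect_equal(rep1$norm_c, row$norm_c)
})
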