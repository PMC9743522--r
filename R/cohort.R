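#' Default cohort geometry
#'
#' The fixed scaled-down genome used by [simulate_cohort()]: a 5 Mb stand-in
#' for the 7q34 neighborhood (`chr7s`) carrying the target gene, and a 2 Mb
#' trans chromosome (`chr3s`) supplying the insertion-translocation partner.
#' The viewpoint mirrors the real design: an 80 kb kept C-terminal anchor
#' `[3.30, 3.38)` Mb and a 140 kb lost N-terminal anchor `[3.38, 3.52)` Mb
#' sharing the breakpoint boundary at 3.38 Mb. The canonical-type event is a
#' ~1.78 Mb tandem duplication `[1.6, 3.38)` Mb placing the partner locus
#' ~1.7 Mb upstream of the gene (outside the 1 Mb peak-calling exclusion
#' flank, like the real canonical partner); the insertion-type event deletes
#' 150 kb at the N-terminal side and inserts a 260 kb segment of `chr3s` in
#' its place (the 151 kb loss / 263 kb insertion mechanism, scaled to the
#' bin grid).
#'
#' @return list with `chrom_lengths`, `anchors` (an [anchor_set()]),
#'   `events` (per fusion type) and `partner_breakpoint`s.
#' @export
cohort_geometry <- function() {
  chrom_lengths <- c(chr7s = 5e6, chr3s = 2e6)
  anchors <- anchor_set("BRAFsim",
                        c_terminal = gi("chr7s", 3.30e6, 3.38e6),
                        n_terminal = gi("chr7s", 3.38e6, 3.52e6))
  list(
    chrom_lengths = chrom_lengths,
    anchors = anchors,
    events = list(
      tandem_duplication = sv_event("tandem_duplication", "chr7s", 1.6e6, 3.38e6),
      insertion_translocation = sv_event("insertion_translocation", "chr7s",
                                         3.38e6, 3.53e6,
                                         source_chrom = "chr3s",
                                         source_start = 5e5, source_end = 7.6e5)),
    partner_breakpoint = list(
      tandem_duplication = gi("chr7s", 1.6e6, 1.61e6),
      insertion_translocation = gi("chr3s", 5e5, 5.1e5)))
}

#' Simulate a Hi-C cohort with one planted fusion
#'
#' Generates `n_samples` contact matrices on the [cohort_geometry()]
#' reference. The fusion sample is simulated as a diploid mixture — one
#' rearranged and one intact haplotype at half depth each — since real Hi-C
#' sees both alleles (and tumors are rarely pure); the other samples carry
#' two intact haplotypes. All samples share a planted compartment
#' checkerboard (common across the cohort, as compartment structure largely
#' is between related samples).
#'
#' @param n_samples Cohort size (default 6).
#' @param fusion_sample Index of the fusion-bearing sample, or `NULL`/0 for a
#'   fusion-free cohort.
#' @param fusion_type `"tandem_duplication"` (canonical-type) or
#'   `"insertion_translocation"` (interchromosomal-type).
#' @param depth Expected read pairs per sample.
#' @param decay_exponent,trans_rate,compartment_boost,compartment_block_bins
#'   Generator parameters; see [simulation_config()].
#' @param bin_size Fine bin width in bp.
#' @param seed Integer seed; each sample uses a derived sub-seed.
#' @return list with `samples` (each: `name`, `matrix`, `truth`),
#'   `anchors`, `partner_breakpoint` (NULL for fusion-free cohorts),
#'   `fusion_sample`, `compartment_labels`, `chrom_lengths`, `bin_size`.
#' @export
simulate_cohort <- function(n_samples = 6L, fusion_sample = 1L,
                            fusion_type = c("tandem_duplication",
                                            "insertion_translocation"),
                            depth = 3e6, decay_exponent = 1, trans_rate = 0.01,
                            compartment_boost = 1.5, compartment_block_bins = 50L,
                            bin_size = 1e4, seed = 1L) {
  fusion_type <- match.arg(fusion_type)
  geom <- cohort_geometry()
  if (is.null(fusion_sample) || length(fusion_sample) == 0L || all(fusion_sample == 0L))
    fusion_sample <- integer()
  identity_genome <- build_derived_genome(geom$chrom_lengths, list(), bin_size)
  labels <- checkerboard_labels(nrow(identity_genome$bins_reference),
                                compartment_block_bins)
  cfg <- function(dp, sd) simulation_config(
    bin_size = bin_size, decay_exponent = decay_exponent, trans_rate = trans_rate,
    depth = dp, compartment_labels = labels,
    compartment_boost = compartment_boost, seed = sd)
  samples <- lapply(seq_len(n_samples), function(s) {
    sseed <- (as.numeric(seed) * 1009 + s * 13) %% .Machine$integer.max
    name <- sprintf("sample_%02d", s)
    if (s %in% fusion_sample) {
      derived <- build_derived_genome(geom$chrom_lengths,
                                      list(geom$events[[fusion_type]]), bin_size)
      hap1 <- simulate_contact_matrix(derived, cfg(depth / 2, sseed))
      hap2 <- simulate_contact_matrix(identity_genome, cfg(depth / 2, sseed + 7))
      mat <- add_matrices(hap1$matrix, hap2$matrix)
      truth <- hap1$truth
    } else {
      sim <- simulate_contact_matrix(identity_genome, cfg(depth, sseed))
      mat <- sim$matrix
      truth <- empty_sv_calls()
    }
    mat$sample <- name
    if (nrow(truth) > 0L) truth$sample <- name
    list(name = name, matrix = mat, truth = truth)
  })
  list(samples = samples, anchors = geom$anchors,
       partner_breakpoint = if (length(fusion_sample))
         geom$partner_breakpoint[[fusion_type]] else NULL,
       fusion_sample = fusion_sample, fusion_type = fusion_type,
       compartment_labels = labels, chrom_lengths = geom$chrom_lengths,
       bin_size = bin_size)
}
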