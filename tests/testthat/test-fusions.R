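write_fusion_file <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("fusion aggregation unions by unordered gene pair", {
  mk <- function(g5, g3, pos5 = 1e6, pos3 = 2e6, sr = 5) {
    data.frame(gene5 = g5, gene3 = g3, chrom5 = "chr7", pos5 = pos5,
               chrom3 = "chr7", pos3 = pos3, split_reads = sr,
               spanning_pairs = 2, stringsAsFactors = FALSE)
  }
  f <- aggregate_fusions(list(
    starfusion = mk("KIAA1549", "BRAF"),
    arriba = mk("KIAA1549", "BRAF", sr = 9),
    infusion = mk("BRAF", "KIAA1549")))   # reversed orientation still one pair
  expect_equal(nrow(f), 1L)
  expect_equal(f$n_callers, 3L)
  expect_equal(f$max_split_reads, 9)
})

test_that("union semantics: a singleton pair survives a priority-gene filter", {
  mk <- function(g5, g3) data.frame(gene5 = g5, gene3 = g3, chrom5 = "chr1",
                                    pos5 = 1, chrom3 = "chr1", pos3 = 2,
                                    split_reads = 1, spanning_pairs = 1,
                                    stringsAsFactors = FALSE)
  noise <- do.call(rbind, lapply(1:50, function(i) mk(sprintf("G%da", i),
                                                      sprintf("G%db", i))))
  one <- rbind(noise, mk("PTPRZ1", "BRAF"))
  f <- aggregate_fusions(list(caller1 = one, caller2 = noise),
                         priority_genes = c("BRAF", "RAF1"))
  expect_equal(nrow(f), 1L)
  expect_equal(f$n_callers, 1L)   # detected by only one of the callers
  expect_equal(sort(c(f$gene5, f$gene3)), c("BRAF", "PTPRZ1"))
})

test_that("malformed rows are skipped with a reported count", {
  d <- data.frame(gene5 = c("A", "", "C", "D"), gene3 = c("B", "X", "C", "E"),
                  chrom5 = "chr1", pos5 = c(1, 2, 3, NA),
                  chrom3 = "chr1", pos3 = c(5, 6, 7, 8),
                  split_reads = 1, spanning_pairs = 1, stringsAsFactors = FALSE)
  p <- write_fusion_file(d)
  expect_message(f <- read_fusion_tsv(p, caller = "x"), "3 malformed")
  expect_equal(nrow(f), 1L)
  expect_equal(attr(f, "n_skipped"), 3L)
})

test_that("caller-count histogram matches a constructed fixture", {
  mk <- function(g5, g3) data.frame(gene5 = g5, gene3 = g3, chrom5 = "chr1",
                                    pos5 = 10, chrom3 = "chr2", pos3 = 20,
                                    split_reads = 1, spanning_pairs = 1,
                                    stringsAsFactors = FALSE)
  # shared by 3, shared by 2, unique to each of 3 callers
  f <- aggregate_fusions(list(
    c1 = rbind(mk("S3a", "S3b"), mk("S2a", "S2b"), mk("U1a", "U1b")),
    c2 = rbind(mk("S3a", "S3b"), mk("S2a", "S2b"), mk("U2a", "U2b")),
    c3 = rbind(mk("S3a", "S3b"), mk("U3a", "U3b"))))
  expect_equal(as.vector(table(f$n_callers)), c(3L, 1L, 1L))
  expect_equal(f$n_callers[f$gene5 == "S3a"], 3L)
})

test_that("distinct junctions are counted with the breakpoint tolerance", {
  mk <- function(p5, p3) data.frame(gene5 = "A", gene3 = "B", chrom5 = "chr1",
                                    pos5 = p5, chrom3 = "chr2", pos3 = p3,
                                    split_reads = 1, spanning_pairs = 1,
                                    stringsAsFactors = FALSE)
  f <- aggregate_fusions(list(c1 = rbind(mk(1000, 5000), mk(1400, 5200),
                                         mk(90000, 5000))),
                         breakpoint_tolerance = 1000)
  expect_equal(f$n_junctions, 2L)
})

toy_genes <- data.frame(
  chrom = c("chr7", "chr7"),
  start = c(1e6, 5e6), end = c(2e6, 6e6),
  strand = c("-", "-"),
  gene = c("PARTNER", "TARGET"), stringsAsFactors = FALSE)

# TARGET exons: 16 exons of 10 kb spaced every 60 kb across [5e6, 5.95e6),
# minus strand so exon 1 sits at the highest coordinates
toy_exons <- data.frame(
  gene = "TARGET",
  start = 5e6 + (0:15) * 6e4,
  end = 5e6 + (0:15) * 6e4 + 1e4, stringsAsFactors = FALSE)

test_that("breakpoints are labeled with genes; intergenic is not an error", {
  calls <- sv_calls(c("chr7", "chr7"), c(1.5e6, 3e6), c("chr7", "chr7"),
                    c(5.5e6, 4e6), sv_type = "DUP")
  ann <- annotate_breakpoints(calls, toy_genes)
  expect_equal(ann$gene1, c("PARTNER", "intergenic"))
  expect_equal(ann$gene2, c("TARGET", "intergenic"))
})

test_that("a break between transcription-order exons 15 and 16 is intron 15", {
  # minus strand: exon 1 = coordinate-highest exon; intron 15 lies between
  # the 2nd and 1st coordinate exons
  pos_intron15 <- 5e6 + 1e4 + 3e4   # between coord-exons 1 and 2 -> intron 15
  calls <- sv_calls("chr7", pos_intron15, "chr7", 5.99e6, sv_type = "DEL")
  ann <- annotate_breakpoints(calls, toy_genes, exons = toy_exons)
  expect_equal(ann$feature1, "intron 15")
  # inside the coordinate-highest exon -> exon 1
  calls2 <- sv_calls("chr7", 5e6 + 15 * 6e4 + 5e3, "chr7", 5.99e6)
  ann2 <- annotate_breakpoints(calls2, toy_genes, exons = toy_exons)
  expect_equal(ann2$feature1, "exon 1")
})

test_that("tandem-duplication orientation puts the downstream gene 5prime", {
  # both genes on the minus strand, as in the canonical fusion: the
  # duplication junction retains the right side at pos1 (PARTNER keeps its
  # 5' end) and the left side at pos2 (TARGET keeps its C-terminal 3' half)
  calls <- sv_calls("chr7", 1.5e6, "chr7", 5.5e6, sv_type = "DUP")
  ann <- annotate_breakpoints(calls, toy_genes)
  expect_equal(ann$gene5, "PARTNER")
  expect_equal(ann$gene3, "TARGET")
  # explicit sides override: a deletion junction reverses the roles
  ann2 <- annotate_breakpoints(sv_calls("chr7", 1.5e6, "chr7", 5.5e6,
                                        sv_type = "DEL"), toy_genes)
  expect_equal(ann2$gene5, "TARGET")
  expect_equal(ann2$gene3, "PARTNER")
})

test_that("planted simulator fusions annotate to the planted gene pair", {
  geom <- cohort_geometry()
  genes <- data.frame(chrom = c("chr7s", "chr7s", "chr3s"),
                      start = c(1.5e6, 3.3e6, 4.5e5),
                      end = c(1.7e6, 3.52e6, 7e5),
                      strand = c("-", "-", "+"),
                      gene = c("PARTNERsim", "BRAFsim", "TRANSsim"),
                      stringsAsFactors = FALSE)
  g_dup <- build_derived_genome(geom$chrom_lengths,
                                list(geom$events$tandem_duplication), 1e4)
  ann <- annotate_breakpoints(g_dup$breakpoints, genes)
  expect_setequal(c(ann$gene1, ann$gene2), c("PARTNERsim", "BRAFsim"))
  expect_equal(ann$gene5, "PARTNERsim")
  g_ins <- build_derived_genome(geom$chrom_lengths,
                                list(geom$events$insertion_translocation), 1e4)
  ann2 <- annotate_breakpoints(g_ins$breakpoints, genes)
  expect_true("TRANSsim" %in% c(ann2$gene1, ann2$gene2))
})
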