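# fusion4c

Detection and characterization of low-frequency gene fusions from Hi-C
contact maps.

## The problem

*RAF*-family fusions — prototypically the *KIAA1549-BRAF* tandem duplication
at 7q34 — drive most juvenile pilocytic astrocytomas, but immune and
vascular infiltration leaves many clinical samples with low tumor purity,
where RNA-seq and short-read WGS miss the event. A rearrangement that fuses
two loci also makes them physically adjacent, so a reference-aligned Hi-C
map shows a strong ectopic contact between the partner regions regardless
of expression. `fusion4c` turns that observation into a tested pipeline for
genomicists working with binned Hi-C matrices and multi-caller SV/fusion
call sets.

## What it computes

**Virtual 4C with anchor-partition normalization.** Three viewpoints on the
target gene: the kept C-terminal anchor *C*, the lost N-terminal anchor
*N*, and their union *BG* (for BRAF: chr7 140,710,000–140,790,000,
140,790,000–140,930,000 and 140,710,000–140,930,000; shipped in
`inst/extdata/braf_anchors.yaml`). Contacts binned at 10 kb are summed into
50 kb bins phased at the C/N boundary, and each bin *b* gets

    norm_C(b) = raw_C(b) / raw_BG(b),   norm_C + norm_N = 1

which cancels the distance bias between the bin and the viewpoint. Fusion
partners appear as peaks in `norm_C` exclusive to the fused sample, scored
by a leave-one-out cohort z-score with an absolute-effect floor
(`detect_partner_peaks()`).

**Contact-matrix infrastructure.** Sparse upper-triangle matrices with COO
text I/O, iterative-correction balancing with a coverage mask,
observed/expected transformation, and breakpoint-anchored coarsening that
conserves total counts exactly.

**A/B compartments.** Per-chromosome scores from the eigendecomposition of
the O/E Pearson correlation matrix (sign fixed by an explicit orientation
track; top-3 eigenvector selection with flagging), plus cross-sample
correlation and average-linkage clustering with TSV/Newick export.

**SV and fusion consensus.** Multi-caller merging under the
double-breakpoint rule (start *and* end within ±1000 bp, inclusive;
single-linkage; type ignored), size (> 10 kb) and support (≥ 2 callers)
filters, matched-normal subtraction, union-based RNA fusion aggregation by
gene pair, and breakpoint annotation (gene, intron in transcription order,
predicted 5′ partner).

**A rearrangement-aware simulator.** Derived genomes with tandem
duplications, deletions, interchromosomal insertions and balanced
translocations; power-law cis decay, compartment checkerboards, flat trans
background, Poisson depth sampling; lift-over back to reference bins with
summed duplicate contributions; multi-caller call-set simulation with
jitter, dropout and false positives. Ground truth is returned alongside
everything, so each downstream claim is testable without controlled-access
patient data.

## Worked example

Simulate a 6-sample cohort in which sample 2 carries a canonical-type
tandem-duplication fusion, extract virtual 4C profiles, and call exclusive
peaks:

```r
library(fusion4c)

cohort   <- simulate_cohort(n_samples = 6, fusion_sample = 2,
                            fusion_type = "tandem_duplication", seed = 42)
profiles <- lapply(cohort$samples,
                   function(s) extract_profile(s$matrix, cohort$anchors,
                                               coarse_factor = 5))
peaks <- detect_partner_peaks(profiles, z_threshold = 4)
head(peaks[, c("sample", "chrom", "start", "end", "n_bins", "peak_z")], 3)
#>      sample chrom   start     end n_bins   peak_z
#> 2 sample_02 chr7s 1480000 2280000     15 38.24891
#> 1 sample_02 chr7s       0  130000      3  5.66153

cohort$partner_breakpoint
#> chr7s:[1,600,000, 1,610,000)  width=10,000
```

Every reported locus belongs to the fusion-bearing sample, and the
top-ranked locus (peak z ≈ 38) spans the planted partner breakpoint at
chr7s:1,600,000 — the duplicated segment whose junction abuts the kept
C-terminal anchor. The remaining smaller loci are the duplication's
coverage footprint in the same sample; fusion-free samples report nothing.

The whole pipeline (simulate → balance → compartments → virtual 4C →
SV consensus → report) runs from a YAML config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "fusion4c"),
             outdir = "demo_out")
```

writing per-sample matrices, weights, compartment tracks, profiles, peak
calls, consensus SVs and a `report.json` naming the fusion sample and
partner locus; reruns with the same config and seed are byte-identical. A
thin command-line wrapper ships in `inst/scripts/fusion4c.R`.

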