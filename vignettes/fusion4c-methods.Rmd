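---
title: "Detecting gene fusions from Hi-C: methods and design notes"
author: "fusion4c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene fusions from Hi-C: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusion4c)
```

## The problem

Juvenile pilocytic astrocytomas and related low-grade gliomas are driven by
gene fusions that constitutively activate a kinase — most often a tandem
duplication at 7q34 fusing *KIAA1549* to *BRAF*, removing BRAF's
auto-inhibitory N-terminal domain while keeping its C-terminal kinase
domain. These tumors are heavily infiltrated by normal cells, so the fusion
allele can sit at a low cell fraction and escape RNA-seq and short-read WGS.
Hi-C offers an orthogonal detection route: any rearrangement that fuses two
loci makes them *physically adjacent* on the derived chromosome, so a
reference-aligned Hi-C contact map shows a strong ectopic interaction
between the two partner regions — a signal that survives low purity because
it is read out against an essentially empty background.

`fusion4c` implements this detection logic as a tested pipeline: a virtual
4C read-out of a target gene's two terminals, compartment-level chromatin
context, and a multi-caller structural-variant consensus layer — exercised
end to end on simulated contact maps with planted rearrangements, so that
every stage has ground truth.

## Virtual 4C with anchor-partition normalization

The core computation fixes three viewpoint intervals on the target gene:
the **C-terminal anchor** (the part kept in the fusion), the **N-terminal
anchor** (the part lost), and their union, the **full-gene background**.
For BRAF on GRCh38 these are chr7 [140,710,000–140,790,000),
[140,790,000–140,930,000) and [140,710,000–140,930,000); the shipped default
(`inst/extdata/braf_anchors.yaml`) uses these verbatim as 0-based half-open
bin edges — they are 10 kb aligned as printed.

Contacts are binned at 10 kb, then summed into 50 kb bins *phased at the
anchor boundary*: one coarse bin edge falls exactly on the C/N boundary so
that kept and lost terminals never share a bin (`coarsen_anchored()`). For
each coarse bin $b$ the profile records

$$\mathrm{raw}_C(b) = \sum_{f \in b}\sum_{a \in C} M_{fa}, \qquad
  \mathrm{norm}_C(b) = \frac{\mathrm{raw}_C(b)}{\mathrm{raw}_{BG}(b)},$$

and symmetrically for N. Because $C$ and $N$ partition $BG$,
$\mathrm{raw}_{BG} = \mathrm{raw}_C + \mathrm{raw}_N$ and
$\mathrm{norm}_C + \mathrm{norm}_N = 1$ exactly on every bin with any
background contact; bins with none are flagged missing rather than divided.
The ratio cancels the dominant distance decay: both numerator and
denominator see (almost) the same decay kernel, so the normalized fraction
is flat in distance while the raw sum falls as a power law. The residual is
a geometric term of order (anchor width)/(distance) — with 80/140 kb anchors
and a 1 Mb exclusion flank it contributes a slope of roughly 0.02–0.03 per
log10 bp, an order of magnitude below the raw trend of about −2; the
acceptance checks therefore bound the mean normalized slope by ±0.05 rather
than asserting an exact zero, which no finite anchor could satisfy.

Raw (unbalanced) counts are summed by default: the normalization is itself a
per-bin ratio against the same anchor, which cancels per-bin coverage bias,
and it keeps the default path free of a balancing prerequisite. A
`use_weights` flag sums balanced counts instead. For trans chromosomes the
same ratio is applied verbatim — there is no distance decay to remove, but
the ratio still cancels anchor-coverage effects and puts cis and trans bins
on one scale.

### Exclusive-peak calling

A fusion shows up as a peak in $\mathrm{norm}_C$ *exclusive to the fused
sample*. `detect_partner_peaks()` formalizes the visual read-out: at each
bin, each sample's fraction is compared with the leave-one-out mean and SD
of the rest of the cohort; a candidate bin has exactly one sample with

* leave-one-out $z >$ `z_threshold` (default 4), **and**
* an absolute excess over the cohort mean of at least `min_effect`
  (default 0.15 on the fraction scale).

The second condition is essential, not cosmetic. With a cohort of $n$
samples the leave-one-out $z$ uses an SD estimated from $n-1$ values, so
under the null it has $t_{n-2}$-like tails: at $n = 6$,
$P(z > 4) \approx 1\%$ *per bin per sample* no matter how deep the
libraries are, which would scatter dozens of spurious "exclusive" bins per
cohort. A planted fusion moves the fraction by ~0.5 while the count-noise SD
at the default depth is ~0.02, so a 0.15 absolute floor removes the
heavy-tail false positives at a negligible cost in power. It also absorbs
genuine but small sample-wide shifts — e.g. a duplicated C-terminal anchor
raises a sample's trans fractions by ~0.1 everywhere, which is real biology
but not a partner locus. An SD floor (`sd_floor`) guards the division, and
bins with exactly zero cross-sample variance are skipped with a warning.

Bins within `exclusion_flank` (default 1 Mb) of the background anchor are
excluded — the viewpoint's own neighborhood interacts strongly in every
sample. Candidate bins separated by at most one bin are merged into loci
(fusion signal decays over several bins), ranked by peak $z$. A 500 kb
reporting view (`exclusivity_report()`) re-bins the *raw* sums and recomputes
the fractions; because the coarser edges are phased at the same boundary,
re-binning is exactly equivalent to direct extraction at 500 kb, and the
test suite pins that equivalence.

## Compartment scoring and cross-sample comparison

A/B compartments are scored per chromosome as the leading structure of the
Pearson correlation matrix of the balanced, observed/expected cis map:
O/E divides each contact by the mean balanced contact at the same
separation (zero-expected diagonals propagate as missing, never as
division errors), and the compartment score is an eigenvector of
`cor(O/E)` scaled by the square root of its eigenvalue. Two conventions are
made explicit rather than guessed:

* **Sign.** An eigenvector's sign is arbitrary, so the score is oriented to
  correlate non-negatively with a user-supplied `orientation_track` — the
  planted A-density on simulations; gene density or GC content on real
  data. The orientation input is mandatory by design.
* **Which eigenvector.** On markedly aneuploid genomes the first component
  can track karyotype rather than compartments. The top three eigenvectors
  are examined and the one most correlated with the orientation track is
  selected; `eigen_flagged` marks any track where that was not the first.

Cross-sample comparison (`compare_tracks()`) uses pairwise-complete Pearson
correlation of scores (robust to per-sample masks) and average-linkage
clustering on `1 − correlation`, with a 50 kb default resolution; the
similarity matrix exports as TSV and the tree as Newick. Low-dimensional
embeddings of the same correlation matrix are deliberately left out of the
testable core: the correlation + linkage object carries the reproducible
content.

## Multi-caller SV consensus

SV callers disagree on breakpoints by tens to hundreds of bp and label the
same rearrangement with different types. The consensus layer merges calls
whose chromosome pairs match and whose start *and* end breakpoints agree
within ±1000 bp (inclusive at the boundary: an offset of exactly 1000
merges, 1001 does not). Type is deliberately ignored during matching (DUP
vs BND for the same event is routine across heterogeneous callers).
Grouping is single-linkage over the pairwise rule — the simplest reading of
"within ±1000 bp of each other" — and is pinned by a brute-force $O(n^2)$
clustering oracle in the tests, so the choice is explicit and testable.
Each group is represented by its medoid member (minimum summed breakpoint
distance, ties by canonical order).

Filtering retains groups supported by ≥ 2 distinct callers with size
strictly over 10 kb; interchromosomal groups carry no size and pass the
size criterion by default. Matched-normal subtraction flags a tumor group
germline when any normal-sample call matches its representative under the
same double-breakpoint rule — an automated stand-in for manual curation of
somatic status, with no claim of replicating expert review. RNA fusion
calls aggregate by *union* over unordered gene pairs (never intersection:
real fusions are routinely reported by a single caller among hundreds of
candidates), with an optional priority-gene subset for targeted review, and
breakpoint annotation reports gene, intron (in transcription order) and the
predicted 5′ partner from strands plus retained sides.

## The simulator: what it emulates, and what it does not

All acceptance evidence rests on the synthetic-data module, so its scope is
stated precisely. `simulate_contact_matrix()` generates contacts in
*derived* coordinates on a rearranged genome: cis pairs at separation $d$
bins get weight $(d+1)^{-\alpha}$ (default $\alpha = 1$, the canonical Hi-C
decay), same-compartment pairs are boosted by a factor ≥ 1 on an A/B
checkerboard, trans pairs get a flat rate, weights are scaled to the target
depth, and counts are Poisson-sampled per pair (shot noise). Counts are
then lifted back to reference bins, duplicated bins receiving the summed
contributions of all derived copies — exactly the mechanism that creates
ectopic junction signal in a reference-aligned map. The event grammar
covers tandem duplication, deletion, interchromosomal insertion (source
segment copied, mirroring the co-occurring duplication observed at the
donor locus for this mechanism) and balanced translocation; breakpoints are
bin-aligned because all downstream analysis is binned.

The default cohort (`cohort_geometry()`, `simulate_cohort()`) is a scaled
stand-in for the real design: a 5 Mb chromosome carrying an 80 kb C-anchor
and 140 kb N-anchor with the boundary at 3.38 Mb, a ~1.78 Mb tandem
duplication placing the partner ~1.7 Mb from the gene (outside the 1 Mb
exclusion flank, like the canonical partner), and an insertion event that
deletes 150 kb at the N side and inserts 260 kb of a 2 Mb trans chromosome
(the 151 kb loss / 263 kb insertion mechanism on the bin grid). Fusion
samples are simulated *diploid* — one rearranged plus one intact haplotype
at half depth — because real Hi-C sees both alleles; a haploid deletion of
the whole N-terminal region would otherwise zero the denominator's N part.
Defaults: depth 3×10⁶ pairs, trans rate 0.01, compartment checkerboard of
50-bin blocks at boost 1.5, 10 kb bins. These sizes keep a 6-sample cohort
simulation around a few seconds, and 20-cohort acceptance sweeps in minutes.

What the simulator does **not** model — and hence what passing tests do not
show about real data: restriction-fragment structure, read-level artifacts
and mapping bias, copy-number-driven coverage trends beyond the planted
events, TADs and loops (decay is smooth), inter-sample biological
variability of compartments beyond independent sampling noise, and sub-bin
breakpoints. The multi-event "catastrophic chromosome" regime is expressible
in the grammar but no recovery claim is made for it.

## Numerical choices and degenerate inputs

* **Balancing** is iterative correction on the symmetric matrix with a
  coverage mask (strictly below the 2% coverage quantile, plus all
  zero-coverage bins), convergence when the relative variance of unmasked
  weighted row sums is ≤ `tol` (default 1e−5), weights normalized to unit
  mean over unmasked bins. Non-convergence warns and is flagged in the
  result, never silent. Externally computed per-bin weights (for instance
  from a karyotype-aware normalization model) can be attached via
  `set_weights()` under the identical contract.
* **Masking** propagates as flagged-missing (`NA`), never as zeros, through
  O/E, compartment scores and profiles.
* **Ties and order.** Consensus representatives break medoid ties by
  canonical breakpoint order; matching is invariant to caller order, and
  outputs are canonically sorted.
* **Determinism.** Every stochastic step takes an explicit seed and restores
  the caller's RNG state; the same configuration and seed reproduce the
  pipeline report byte-identically.
* **Coordinates.** 0-based half-open everywhere; COO text stores 0-based
  bin indices; short terminal bins are retained so coarsening conserves the
  genome-wide total exactly.

## Known limitations

The exclusivity rule assumes a cohort in which at most a minority of
samples share any given partner; a partner recurrent in most of a cohort
(e.g. the canonical fusion in a purely canonical cohort) suppresses its own
signal under leave-one-out scoring — by design, matching the read-out of
"exclusive to the fused sample(s)" against a mixed cohort. Single-sample
detection without a cohort is out of scope, as are loop-level significance
models, TAD calling and sub-compartments.
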