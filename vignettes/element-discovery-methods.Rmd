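---
title: "Methods: conserved-element discovery and deletion qPCR analysis"
author: "crescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-element discovery and deletion qPCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescan)
```

# The scientific problem

Olfactory receptor gene clusters are controlled by small, deeply conserved
cis-acting enhancers that sit between genes, outside coding sequence and
outside repeats. In the mouse trace amine-associated receptor (TAAR)
cluster — 15 receptor genes within roughly 200 kb — two such elements
("T-elements") were found by combining three filters: phylogenetic
conservation, a non-repetitive sequence requirement, and an intergenic
location. The elements carry multiple homeodomain (HD) binding sites with
core consensus `TAATNN`, a handful of Olf1/Ebf-like (O/E) sites matching
the degenerate consensus `YCCCNNGGGR`, a triple repeat of `TAATGA` within
a 206-bp window that occurs once in the whole cluster, and a ~30-bp
homology block shared between the two elements. Deleting the elements and
reading out cluster gene expression by qPCR (the 2^-ΔΔCt method)
quantifies their necessity.

`crescan` packages that discovery-and-quantification procedure as reusable,
tested components: interval arithmetic for the search space, conservation
segment calling, degenerate motif scanning, cross-species motif
conservation, shared-homology discovery with false discovery control, an
integrated candidate caller, and the qPCR deletion-effect analysis. A
synthetic-data module generates every input with recorded ground truth so
the whole pipeline is testable offline.

# Coordinates and the search space

Published coordinates mix conventions: the element coordinates are
consistent with end-exclusive arithmetic (e.g. a 698-bp element printed as
`23,806,280-23,806,978`), while CRISPR deletion coordinates are consistent
with fully-closed arithmetic (a 993-bp deletion printed as
`23,806,234-23,807,226`). Rather than silently picking one convention,
`parse_interval()` takes an explicit tag
(`one_based_fully_closed`, `one_based_end_exclusive`,
`zero_based_half_open`) and all lengths round-trip exactly:

```{r coords}
interval_length(parse_interval("chr10: 23,806,234-23,807,226",
                               "one_based_fully_closed"))
interval_length(parse_interval("chr10: 23,806,280-23,806,978",
                               "one_based_end_exclusive"))
```

Internally every interval is a `GRanges` in the Bioconductor convention
(1-based, fully closed). This is a deliberate design choice: `GRanges` is
the field-standard container, its `IRanges` backbone supports zero-width
ranges for degenerate intervals, and all interval arithmetic
(`intergenic_regions()`, `subtract_mask()`) flows through
`GenomicRanges` set operations, with half-open-style adjacency semantics
(intervals sharing only a boundary do not overlap).

The gene footprint used by the intergenic filter is the whole transcript
interval, not exon-only, plus standalone pseudogene fragments — the
discovery procedure excludes UTRs, introns of annotated genes, and
pseudogene remnants from the candidate space.

# Conservation

Two kinds of evidence are supported and share one representation, the
per-base `conservation_track` (missing coverage is `NA`, never zero):

* **External scores** (phyloP-style tracks) read from bedGraph or wiggle.
  The package never recomputes the phylogenetic statistic itself.
* **Identity proxies.** `percent_identity_profile()` computes
  PipMaker-style percent identity in a centered window over a pairwise
  alignment (reference-gap columns carry no score; a gap in the other row
  counts as a mismatch; edge windows are truncated, not dropped).
  `derive_conservation()` computes, per reference base of a multi-species
  alignment, the fraction of species whose aligned base equals the
  reference — a simple species-agreement proxy in `[0, 1]`.

`call_conserved_segments()` finds maximal runs of bases at or above a
threshold, bridges sub-threshold gaps up to `merge_gap` (default 20 bp),
and discards runs shorter than `min_len` (default 50 bp; both on the order
of magnitude of the 345–698-bp elements being sought). The default
threshold is the 90th percentile of the track, appropriate when roughly a
tenth of the supplied span is expected to be conserved; an absolute
override is available and is what the integrated pipeline uses (below).

# Motif scanning

`scan_iupac()` is an exact degenerate-motif scanner: every window that
satisfies the IUPAC pattern on the requested strand(s) is reported, with
no greedy masking, so overlapping matches and double-stranded hits at a
palindromic footprint are all visible. An `N` in the sequence satisfies
only a pattern position that is itself `N` — unknown bases never match a
constrained position. Because the strandedness of published per-element
counts is not always stated, the candidate caller annotates forward-only
and both-strand counts side by side.

`find_motif_clusters()` implements the "k copies within w bp" rule. The
span semantics are first-match start to last-match end, inclusive — under
this rule three 6-bp matches whose starts are 0, 100, and 200 span exactly
206 bp and qualify at `window = 206`. A pairwise-distance alternative
(`semantics = "pairwise"`) is provided. Reported clusters are maximal
qualifying groups, each reported once, in coordinate order.

# Cross-species motif conservation

`conserved_motif_instances()` decides whether a motif instance is
phylogenetically conserved: each reference-strand match is projected
through the alignment (`project_position()` maps ungapped reference
positions to columns), and each species' gap-stripped window over the
footprint columns is tested. Support is binary per species — the window
must have exactly the pattern length and satisfy the pattern (no partial
credit); with `exact_variant = TRUE` it must equal the reference variant
letter for letter, distinguishing "any HD site at the homologous position"
from "the same hexamer in every species". Both modes are exposed because
published conservation calls do not state which rule was used. The default
minimum support is 0.8 of all species (reference included); the studies
this models describe conservation "across eutherian mammals" without a
numeric rule, and 0.8 of a 16-species panel tolerates a couple of
divergent or misaligned rows while still demanding broad agreement.

# Shared homology and database scanning

`find_shared_blocks()` finds ungapped homology blocks between two
elements: exact k-mer seeds (default 12) on both strands, X-drop
extension (match +1, mismatch −4, drop 12, trimmed back to the score
maximum), deduplication, then length and identity filters (defaults 30 bp,
0.9). The penalties are deliberately strict so that a block planted
verbatim is recovered at identity 1.0 rather than diluted by lucky flank
matches; there is no gapped extension — the target is short, contiguous
shared motifs, not general local alignment.

`iupac_match_pvalue()` gives the exact probability that one random window
from a 0-order background satisfies a degenerate pattern (product over
positions of summed allowed-base frequencies).
`scan_database_with_qvalues()` turns that into a FIMO-style screen: per
window an exact match probability (in `mismatch` mode, the exact
Poisson-binomial tail of the match count), Bonferroni over the scanned
windows of each target (both strands), then Benjamini–Hochberg across
targets. The background defaults to frequencies estimated from the
database itself, matching common practice for motif screens. Published
q-values for specific enhancer databases depend on the exact database
sequences and tool internals and are not reproduced here; the package's
claim is calibration (nulls rarely clear q < 0.05) and sensitivity (a
planted query wins decisively), both under test.

# The integrated candidate caller

`call_candidates()` chains the filters exactly as the discovery procedure
does: conserved segments ∩ intergenic space ∩ unmasked space, then motif
annotation, then a deterministic ranking (conserved-HD count, mean
conservation, coordinate). Motif content annotates and ranks but does not
gate by default — the discovery criteria are the three filters, and HD
content was examined afterwards; a `require_hd` gate exists for stricter
use. Candidate boundaries are the conserved-segment boundaries clipped to
the allowed space; no attempt is made to define "true" element edges,
which the underlying biology leaves unspecified.

For its default conservation rule the pipeline smooths the track with a
100-bp rolling mean and applies an absolute cutoff of 0.9 on the
species-agreement scale. The percentile default of the segment-calling
module is not appropriate here: a quantile rule marks a fixed fraction of
the span as conserved, but in a 200-kb cluster the true elements cover
only ~0.5% of the sequence, so a percentile threshold would either flood
the caller with background or depend fragilely on the planted fraction.
An absolute agreement cutoff of 0.9 sits far above the background
agreement of a typical mammalian panel (~0.8 on this proxy at realistic
divergence) and below the near-perfect agreement of genuine elements, and
the 100-bp smoothing window suppresses single-base noise while blurring
element boundaries by at most ~50 bp — small against 345–698-bp elements
and harmless under the reciprocal-overlap criterion used in validation.

# The synthetic-data module

`simulate_cluster()` emulates the studied system: a 200-kb cluster with
15 two-exon genes, a pseudogene fragment, ~10% repeat coverage, and two
intergenic elements (700 and 345 bp, placed in the first and sixth
intergenic gaps, mirroring the real layout). Each element carries seven
forward-strand `TAATNN` sites (four flagged conserved, with the published
variants), three O/E sites (not conserved), and a common 30-bp block
containing the two shared words `TTGCATCA` and `TAAAGTTTTC`; the second
element carries the `TAATGA` triad within a 206-bp window. Because the
point of the generator is to make the planted truth exactly recoverable,
incidental background words that would blur the census are scrubbed: the
element bodies are cleared of chance `TAAT`/`ATTA` words and chance O/E
windows, and the cluster is cleared of chance `TAATGA` triads outside the
elements. Conserved decoys are additionally planted inside an exon and
inside a repeat so that the intergenic and mask filters are genuinely
exercised rather than vacuously satisfied.

`simulate_orthologs()` uses a star phylogeny: each of 15 non-reference
species is derived independently from the reference by per-site
substitution (probability `p` per branch, uniform over the three
alternative bases), with branch probabilities ramping 0.08–0.35 — a
spread that produces background agreement around 0.8, similar to a
eutherian panel at the proxy's resolution. Inside elements the rate is
multiplied by 0.05; conserved motif footprints are frozen (multiplier 0)
and non-conserved planted motifs mutate at the background rate, so the
support rule separates them cleanly. No indels are introduced in this
generation of the simulator, so the alignment is trivially positional;
gap handling in the consumers is tested with hand-built gapped fixtures
instead. What the generator therefore does *not* emulate: indel
turnover, alignment error, repeat families with internal structure,
GC heterogeneity, and phylogenetic correlation between species (a star,
not a tree). Passing the closed-loop tests shows the pipeline recovers
planted structure under realistic noise levels; it does not certify
performance on real alignments with indels or misalignment.

`simulate_qpcr()` generates Ct tables as
`Ct = baseline(gene) + sample offset − log2(fold) + noise`, with a
per-sample global offset (s.d. 0.5 cycles, representing RNA input
variation — this is what makes housekeeping normalization do real work),
biological noise of 0.2 cycles, technical-replicate noise of 0.05 cycles,
and five animals per genotype with three technical replicates — the
published experiment's design. Abolished expression is modelled as a
fold floor of 2^−10 rather than missing Ct, keeping the estimator total;
true censoring can be layered on by the user.

# qPCR deletion-effect analysis

ΔCt is computed per sample as the target Ct minus the arithmetic mean of
the housekeeping Cts (`Bgus`, `Gnal`, `Ncam` in the modelled experiment).
"Normalizing by the geometric mean of the housekeeping genes" is exactly
this: the geometric mean of the expression quantities 2^−Ct corresponds
to the arithmetic mean of the Ct values, and the equivalence is asserted
in the unit tests. ΔΔCt is the mutant-minus-control difference of group
mean ΔCt, fold = 2^−ΔΔCt, so the control group has fold 1 by
construction. Hypothesis testing is a two-sided one-way ANOVA on the raw
ΔCt values per gene (not on folds), with Dunn–Šidák family-wise
adjustment `p_adj = 1 − (1 − p)^m`; a gene with zero within-group
variance is assigned p = 1 when the group means agree and p = 0 when they
do not. Effects are classified as `abolished` (fold ≤ 0.05 and
significant), `reduced` (fold < 1 and significant), or `spared`; the 0.05
fold threshold is a package default, exposed in the interface, since the
modelled studies report significance but no numeric fold rule.

```{r qpcr}
sim <- simulate_qpcr(seed = 42)
res <- qpcr_pipeline(sim$ct, sim$truth$housekeeping, control = "wt")
head(res$effects)
```

# Numerical and validation choices

* **Determinism.** Every simulator takes a seed and is byte-reproducible;
  `call_candidates()` ranks with explicit tie-breaks (coordinate order
  last) and `report_json()` emits byte-identical JSON for identical runs.
* **Oracles.** The scanner is checked against a naive sliding-window
  oracle (and against `Biostrings::matchPattern` as an independent
  implementation), segment calling against run enumeration, cluster
  detection against exhaustive enumeration, interval arithmetic against
  base-wise membership, block finding against an all-diagonals
  exact-match oracle, match probabilities against full enumeration of
  short words, BH q-values against a hand-rolled BH.
* **Problem sizes.** The validation suite runs 50 seeded 200-kb clusters
  through the full discovery loop for recall/precision, 100 random
  500-bp pairs for the shared-block null, 150 random databases for FDR
  calibration, and 200 replicate qPCR experiments for fold recovery —
  sizes at which the binomial uncertainty of the checked rates is small
  relative to the 0.9/0.95 acceptance margins.
* **Degenerate inputs.** Empty search spaces, empty databases, empty
  candidate sets, and zero-width intervals are all legal values, not
  errors; missing required inputs (no genome, missing housekeeping
  measurements, absent control group) raise immediately.

# Known limitations

* Conservation thresholds are calibrated for the species-agreement proxy;
  applying the absolute default to phyloP-scale scores requires setting
  `cons_threshold` (or the percentile rule) appropriately.
* The shared-block finder is ungapped by design and will fragment a
  homology interrupted by indels.
* Database scanning controls FDR across targets with a conservative
  Bonferroni within target; with very long targets this loses power
  relative to exact order-statistic corrections.
* The ortholog simulator's star phylogeny has no shared internal
  branches, so derived conservation scores are slightly less dispersed
  than under a real tree at equal mean divergence.
* Real-genome integration (a full receptor cluster with its annotation,
  repeat mask, and phyloP track) exercises exactly the same code paths
  through the file readers, but is not part of the offline validation
  suite.
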