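---
title: "Closing assembly gaps with long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing assembly gaps with long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanweld)
```

## The problem

Short-read assemblies of complex genomes are fragmented: repeats longer
than the read length cannot be traversed, and scaffolding leaves runs of
`N`s (assembly gaps) between neighbouring contigs. Error-prone long reads
(PacBio CLR-class, ~10–15% error dominated by insertions and deletions)
can span many of these gaps, but two things make naive gap filling
dangerous: reads align ambiguously around repeats — precisely where gaps
live — and raw read sequence is far too inaccurate to insert directly.
spanweld closes intra-scaffold (and optionally inter-scaffold) gaps with a
pipeline built around three safeguards: comprehensive repeat annotation
feeding a strict alignment filter, conflict resolution on a scaffold
graph, and a consensus + validation stage that prefers leaving a gap open
over closing it wrongly.

## Repeat annotation

Four annotations are computed on the assembly's contigs and then
*homogenized*:

1. **Low complexity** (`dust_mask()`): windows scored by triplet
   over-representation, \(\sum_t c_t (c_t - 1)/2 \,/\, (l - 1)\), masked
   above a threshold of 2 in 64 bp windows.
2. **Tandem repeats** (`tandem_mask()`): positions where the sequence
   matches itself at period \(\le\) 100 bp over \(\ge\) 60 bp (80%
   windowed match fraction, tolerating divergence).
3. **Self-alignment repeats** (`self_alignment_mask()`): positions covered
   by \(\ge\) 4 alignments to other genomic regions (both intervals of
   each off-diagonal alignment count).
4. **Read-coverage repeats**: with reads sampled uniformly, the depth at a
   unique locus is Poisson with mean the global coverage \(C\)
   (\(P(k) = C^k e^{-C}/k!\)). `compute_cmax()` returns the smallest
   \(m\) with \(P(X > m) <\) `tail_prob`; positions deeper than
   \(C_{max}\) are masked, as are positions where *improper* alignments
   (unaligned read tails not explained by a read end or a contig
   boundary) exceed \(C/2\).

The tail probability (default `1e-3`) is a package choice: it keeps
\(C_{max}\) near \(C + 3\sqrt{C}\), small enough to catch collapsed
repeats at two-fold depth while expecting well under one false masked
locus per 10 kb of unique sequence. Homogenization (`homogenize()`)
transfers masks onto the reads through the alignments and back through
*all* alignments of each read, so a repeat annotated on one copy
propagates to every copy; the result always contains the input union and
is idempotent up to trace granularity.

A note on "proper": the pipeline maps reads against contigs, so an
alignment clipped at a contig boundary (a read reaching into a gap) is
*not* treated as a repeat signal — only clipping in the middle of a
contig is. Without this, every gap-flanking locus would be masked by its
own spanning reads.

## Alignment filtering and the scaffold graph

`filter_reliable()` keeps alignments that are proper, strongly anchored
(\(\ge\) 500 bp of the aligned reference outside the homogenized mask —
summed, not necessarily contiguous), not fully contained in a contig, and
unambiguous (two retained alignments of one read may overlap by at most
the 100 bp allowance in read coordinates; violating reads are dropped
entirely, trading sensitivity for accuracy).

The scaffold graph gives every contig four nodes (`pre`, `begin`, `end`,
`post`); contig and input-gap edges are seeded first, then each read
contributes spanning edges between consecutive alignments and extension
edges at its unaligned ends — never transitive edges. Conflicts (a contig
end with two candidate partners) are resolved by a deliberate, crude
margin rule: the best edge is kept only if its read support is \(\ge 3\times\)
every competitor's, with input-gap edges boosted \(6\times\); otherwise
all competitors are discarded. Small cycles caused by reads skipping a
short intermediate contig are repaired first by re-aligning the skipping
reads at increased sensitivity (error ceiling +5 percentage points,
halved seed requirements — the specific numbers are package choices).
Edges with fewer than 3 spanning reads are pruned (no trustworthy
consensus from 1–2 reads; `allow_single_reads` inserts the raw read for
experts).

## Pile-up consensus

Reads of a surviving edge (spanning plus extending) are cropped via their
traces to common reference positions, reverse-complemented into a common
"gap frame", and capped at 3 kb of retained flank — enough for anchoring
and validation while bounding the quadratic pairwise work.

Read-to-read local alignments are chained on a weighted DAG: node weight
\(-\)(mean bp covered on the two reads); an edge between alignments
\(x, y\) exists iff \(x\) starts strictly before \(y\) on both reads in
the same orientation, \(\mathrm{gapSizeDiff}(x,y) < 1000\) bp, both
per-read gaps are \(< 10{,}000\) bp, and the relative overlap (on either
read, against the shorter alignment) is \(\le 0.3\); the edge weight is
\(\mathrm{gapSizeDiff} + 0.1\max(|gap_A|, |gap_B|)\). Minimum-weight
paths are the chains; ties break toward more aligned bases, then the
leftmost start.

Window-based intrinsic quality values (mean per-base difference rate of
the chained alignments covering each 100 bp window; uncovered windows
worst) pick the reference read: the spanning read with the fewest
windows in the pooled worst 8%.

The consensus itself is two-stage. A banded partial-order alignment
graph is seeded with the reference read; every other read is aligned to
the graph and integrated with per-column fusion, and the draft is the
heaviest edge bundle. This stage was chosen after a plain
reference-voting consensus proved structurally limited: votes against a
single erroneous reference mis-place the same indels in *every* read
near the reference's own errors, so majorities cannot remove them. POA
accumulates support for the true alternative independently of any one
backbone. The draft is then polished by windowed majority voting (100 bp
windows advancing 50 bp: a strict-majority identical realization wins,
else column plurality with ties to the draft), which is exact on
error-free pile-ups. Measured on simulated 13%-error pile-ups over a
2 kb truth, consensus identity is roughly 96% at depth 3, 98% at depth
5, 99.6% at depth 10 and 99.9% at depth 20 — the accuracy climb with
depth is why edges under 3 reads are pruned and why 15–20× coverage is
the practical operating point.

Finally `anchor_insertion()` aligns the consensus ends to the retained
flanks (free end gaps), requires \(\ge\) 95% identity over at least half
the anchor length, and places the insert sites at the innermost exact
run of \(\ge\) 24 matching bases — long enough to be unique against 13%
read error — so contig sequence outside the anchors is never modified.

## Application, validation, modes

`apply_insertions()` supports three modes: `intra_only` (default) closes
only gaps present in the input scaffolding; `intra_and_inter`
additionally joins scaffolds end-to-end; `free_scaffolding` rebuilds
scaffolds from read evidence alone. Candidate selection itself never
depends on the mode.

`validate_gaps()` re-maps all reads to the closed assembly and examines
each former gap ±1000 bp: the closure passes iff \(\ge\) 3 unchained
local alignments span the whole region *and* the minimum continuous
alignment coverage — the count of alignments completely covering a
sliding 500 bp window — exceeds the threshold (user-given, or 50% of the
haploid coverage \(0.5\,C/\mathrm{ploidy}\)). Failing insertions revert
to the original N-run, byte-identically. Validation is single-pass: all
pending insertions are applied together, validated, and the final
assembly rebuilt from the passing subset; a revert can in principle
change a neighbouring region's coverage, which we accept rather than
iterating to a fixed point. Regions shorter than the window (not
addressed by the published rule) are evaluated as a single window.

## Benchmark construction and evaluation

The synthetic side mirrors a realistic ground-truth scenario:

* `simulate_genome()` plants interspersed repeat families (master copy
  plus per-copy substitution divergence) and tandem arrays in a uniform
  background; the planted coordinates are the truth repeat annotation.
* `simulate_reads()` samples read starts uniformly over contigs, lengths
  log-normal (mean 25 kb by default, truncated at contig ends), and
  corrupts bases i.i.d. at 13% split 55/25/20 between insertions,
  deletions and substitutions — the CLR-like indel-dominant profile. The
  55/25/20 split is a package choice; the error rate and length scale
  follow common CLR practice.
* `make_test_assembly()` disassembles the reference into contigs and
  replaces true sequence with N-runs of *identical* length, either at
  sampled positions (biased toward planted repeats, since real gaps sit
  in repeats) or lifted over from a fragmented assembly via unique 500 bp
  flank placements with \(\ge\) 80% matching bases; gaps under 10 bp or
  within 3 kb of a pre-existing gap are skipped.
* `find_closable_gaps()` flags gaps spanned (plus 500 bp flanks) by
  \(\ge\) 3 reads — the sensitivity ceiling of any closer.
* The evaluator locates the test contigs in a result by exact, unique
  search (duplicates pre-excluded with 300 bp cropped flanks; optional
  mismatch-tolerant recovery), classifies each gap as
  closed/unclosed/unknown/broken by the published rules, and scores
  closed gaps by global-alignment identity, matches over alignment
  columns — indels count as errors, so 19 correct bases of a 20 bp gap
  score 95%.

What the synthetic data does *not* emulate: chimeric reads, missed
adapters, coverage biases, haplotype variation, and base-composition
skew. Passing the synthetic suite therefore demonstrates the pipeline's
logic and its accuracy under the stated error model, not performance on
real instrument data.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; AGP is written 1-based,
  BED 0-based, PAF with query coordinates always on the read's forward
  strand.
* The built-in aligner is a seed-and-extend banded edit-distance search
  (11-mer seeds, diagonal clustering, best-subpath trimming); ties in the
  traceback prefer diagonal moves so indel placement is reproducible.
  It serves the pairwise contracts (cycle repair, anchoring, identity,
  flank lift-over); bulk mapping goes through minimap2.
* Pile-ups deeper than 24 reads are downsampled (spanning reads first);
  each read is chained against at most 6 partners for the quality
  estimates. Both bounds are accuracy-neutral in our measurements and
  keep the quadratic stage linear in coverage.
* Terminal N-runs in input scaffolds are preserved but never treated as
  closable gaps. Empty consensus cores (anchors meeting exactly) are
  legal and close a gap to zero inserted bases.
* Tie between two equally supported conflicting edges: both are dropped
  (the margin rule with margin 3 can never hold at a tie).

## Problem sizes used by the test-suite

The shipped tests exercise the full pipeline on a 500 kb genome with 20
introduced gaps (truth lengths 50–5000 bp, placed near planted repeats)
at 20× simulated coverage, and a scaled coverage sweep (5–25×) on a
250 kb genome with 10 gaps; unit fixtures are 10–120 kb. These sizes keep
the whole suite comfortably reproducible on a laptop while leaving every
algorithmic path exercised at realistic depths.

## Known limitations

* Consensus accuracy at depth 3–5 (~96–98%) is below what a
  model-based caller could reach; the validation stage is the backstop.
* `intra_and_inter` joins scaffolds pairwise end-to-end; chains of
  multi-scaffold joins through short free contigs are only fully handled
  by `free_scaffolding`.
* Circular chromosomes and haplotype-aware (diploid) consensus are out
  of scope; heterozygous loci will validate against pooled coverage.
* The evaluator requires gap closers to leave contig interiors intact
  (as the published comparison does); heavily polished outputs need
  `recover_imperfect`.
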