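---
title: "Reconstruction and null-model analysis of chromoanagenesis events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction and null-model analysis of chromoanagenesis events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrtools)
```

This vignette documents the models and procedures behind `cgrtools`, the
choices made where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## Scope and assumptions

The package targets one class of event: a *single-chromosome,
copy-number-neutral* complex rearrangement — a set of reference segments that
partition the chromosome exactly once, reordered and/or inverted, joined by
breakpoint junctions. Translocations, duplications, deletions and other
copy-number-bearing rearrangements are out of scope throughout; the
copy-number-neutral state enters the mechanism inference as an explicit flag.

All internal coordinates are 1-based and inclusive, matching the karyotype
and VCF conventions in which breakpoints are reported. BED input/output is
converted at the boundary (0-based half-open on disk). A cut site `x` always
means "cut between positions `x` and `x + 1`", which makes segment
partitioning unambiguous.

## Derivative-path assembly

A breakend is a position plus a *side*: which flank of the cut the retained
sequence lies on. `assemble_path()` proceeds in four steps:

1. every breakend implies a cut (`pos` for `left_of_cut`, `pos − 1` for
   `right_of_cut`);
2. implied cuts within `merge_tolerance` of each other are unified by
   single-linkage into one cut site placed at the midpoint, rounded down.
   The default of 100 bp reflects that the two breakends flanking a single
   physical disruption typically differ by a small resection (13 bp in the
   packaged index case), so exact-position pairing would be too strict;
3. each cut must then be used by exactly one left-side and one right-side
   breakend — violations raise "non-linear architecture" errors naming the
   offending junctions (breakend used twice, dangling end);
4. a walk starts at the segment containing reference position 1 (the
   p-terminal segment is the mandatory path start and must be entered in
   direct orientation) and follows junction pairings end-to-end. The walk
   must visit every segment once and terminate at the segment containing
   the last reference base; cycles and branches are rejected.

**Inversion counting.** Each segment carried in inverted orientation is one
inversion event; an event is pericentric when the segment's reference
interval contains the *centromere midpoint*. Using the midpoint rather than
the full centromere interval makes the test robust to the differing
centromere annotations across reference builds. Adjacent inverted segments
are *not* collapsed into one event: the packaged index case counts its four
inverted segments as four events, matching how such events are described
cytogenetically, but we do not claim this convention generalizes — a
different study might reasonably count a contiguous inverted run as one
event.

**Junction emission.** `junctions_from_path()` emits one junction per
non-reference adjacency. A subtlety: a random shuffle can re-create a
reference join (two segments that end up adjacent, in order, both direct),
which physically is no junction at all. The synthetic generator
`generate_case()` therefore emits junctions for *every* adjacency, making
`assemble_path()` reproduce its truth path exactly, while
`junctions_from_path()` on an arbitrary path round-trips to the *normalized*
path (reference-adjacent direct runs merged). Both properties are enforced
by tests.

## Junction signatures

The caller takes a *bundle*: proximal flank (retained sequence ending at the
centre base), distal flank (retained sequence starting at the centre base),
and the observed junction sequence. It anchors the observed sequence on each
flank with a short exact seed (up to 12 bp, shrinking for very short
sequences), extends exactly, and reads the signature off the overlap
arithmetic: with `a` the maximal proximal match from the 5′ end, `b` the
maximal distal match from the 3′ end and `n` the observed length,

* `a + b − n > 0` — microhomology of that total length (the scan extends on
  both sides of the nominal transition, so the value is the *total
  ambiguous overlap*);
* `a + b − n = 0` — blunt join;
* `a + b − n < 0` — insertion of the unmatched middle.

Matching is exact by design: the features being called are 0–7 bp, below any
meaningful mismatch tolerance; fuzzy matching is deliberately not offered.
A junction sequence whose ends match the flanks over fewer than
`min(8, n/3)` bases is rejected as inconsistent rather than force-called.

`search_template()` scans both flanks, forward and reverse-complement, for
an exact occurrence of the inserted sequence starting within ±50 bp of a
breakend (configurable; the window never exceeds the available flank). The
hit with the smallest absolute offset wins; ties break proximal before
distal, then forward before reverse-complement. Templates shorter than 3 nt
are not reported — a 1-nt "template" is uninformative.

**One-bp ambiguity.** A single inserted base that equals the base just
beyond either breakend could equally be read as a 1-bp microhomology under a
shifted break assignment. The caller reports what the overlap arithmetic
supports and sets an `ambiguous` flag rather than silently resolving the
choice.

**Mechanism inference** applies conventional thresholds, exposed as
arguments: NHEJ-compatible requires copy-number neutrality, microhomology
≤ 1 bp and insertions ≤ 10 nt at every junction; MMEJ-compatible requires
microhomology in the 2–25 bp band; loss of copy-number neutrality or a
templated insertion ≥ 10 nt flags replicative mechanisms. The rules are
applied in that precedence order and the fired rule is echoed in the
rationale. The label is a pure, order-invariant function of the call set.

## The Monte Carlo null model

The null mirrors the observed event class: `n_segments − 1` distinct cut
sites drawn uniformly (without replacement — whether simulated breakpoints
may coincide is not prescribed anywhere we know of, and distinct sites match
the biology of distinct breaks), first and last segments positionally
static, middle segments uniformly permuted, each independently inverted with
probability 0.5. Defaults (7 segments, 10,000 replicates, p = 0.5) are the
study conditions of the packaged index case.

Two statistics are computed per replicate:

* **clustering** — the "average distance between breakpoints" admits two
  readings, and the package implements both behind a switch: the mean over
  all unordered pairs (the standard dispersion reading, sensitive to the
  full configuration; the `clustering_stat()` default) and the mean
  consecutive gap, which degenerates to `range/(n − 1)`. `run_simulation()`
  always computes and reports both, because analyses in the literature do
  not always state which was used; for the packaged index case the
  consecutive-gap variant reproduces the originally reported p-value.
  The p-value is the fraction of replicates *strictly* smaller than the
  observed value (a replicate counts as more clustered only if its average
  distance is smaller);
* **fusion enrichment** — by default the count of junctions whose two
  breakend positions fall in two *distinct* protein-coding genes
  (`junction_fusion`); the `breakpoint_in_gene` mode instead counts cut
  sites inside any gene. The p-value is the conventional upper tail
  (replicates ≥ observed). Both comparison directions are echoed in the
  output metadata.

Empirical p-values default to the plain proportion `k/R`, matching how such
values are usually printed; the `(k + 1)/(R + 1)` correction, which can
never return exactly zero, is available via `pvalue_correction`.

Randomness is a single seeded stream consumed sequentially; given the same
seed, results are bit-identical. Replicates are not parallelized — at the
default 10,000 replicates a run takes seconds on one CPU, so the extra
machinery of per-replicate RNG streams was not warranted.

## The synthetic-data generator

`generate_genes()` draws non-overlapping gene intervals with exponential
lengths; overlaps are rejection-sampled and exceeding the retry budget
raises rather than silently relaxing disjointness. The chromosome-6-like
default used in the acceptance analysis (1,048 protein-coding genes of mean
length 65 kb, ~40% coverage) matches the approximate protein-coding gene
count of human chromosome 6 and a typical mean gene length; it is a
plausibility stand-in, not a replica — real analyses should supply a real
annotation BED, since the identity of which breakpoints land in which genes
carries the entire fusion signal.

`generate_junction_bundle()` plants a requested signature into random
flanks such that it is the *unique maximal* call: planted microhomology is
shared between the proximal end and the distal flank with the next base
breaking the extension on both sides; planted insertions have their first
and last bases blocked from extending into either flank; chance occurrences
of an insertion within the template window are destroyed by point mutations
(protecting the planted origin), so a non-templated insertion has no
template hit and a templated one has exactly the planted origin as its
closest hit. Construction is verified by re-calling the bundle and retried
with fresh randomness up to 1,000 times before raising.

What the generator does *not* emulate: sequencing reads, alignment noise,
Sanger trace artefacts, repetitive reference context (flanks are i.i.d.
uniform bases), or copy-number change. Passing tests therefore demonstrate
correctness of the calling logic on clean, pre-trimmed junction sequences —
the package's declared input contract — not robustness to upstream
alignment errors.

## Test problem sizes

The test suite exercises: 500-case assembly round trips and 1,000
signature fixtures against brute-force oracles (full-enumeration overlap and
template scans that share no code with the callers); p-value uniformity
under the null (200 trials of 200 replicates, Kolmogorov–Smirnov p > 0.01);
a 10,000-replicate run with per-replicate conservation checks; and a
small-instance cross-check where a length-30, 3-segment chromosome is
exhaustively enumerated and compared with the Monte Carlo distributions.
These sizes were chosen to give the property tests real statistical teeth
while keeping the default suite in the low minutes on one CPU.

## Known limitations

* Single chromosome only; no translocation chains across chromosomes.
* The observed fusion count is only as meaningful as the supplied
  annotation; with the synthetic annotation it is a demonstration value.
* The packaged index-case junction table reconstructs four of the six cut
  positions from published segment sizes (only the *ARID1B* breakends are
  base-pair precise); quantities that depend on exact positions — notably
  the clustering statistic — inherit that approximation, though the
  consecutive-gap statistic depends only on the outermost breakpoints,
  which are the best-constrained.
* VCF support is read-only and limited to BND bracket records and symbolic
  `<INV>`.
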