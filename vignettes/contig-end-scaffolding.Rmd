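---
title: "Scaffolding large contigs from contig-end Hi-C contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding large contigs from contig-end Hi-C contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Hi-C read pairs link genomically proximal loci, and the link density decays
steeply with genomic distance: two adjacent contigs share links almost
exclusively through their neighboring ends (typically within a few Mb of the
junction). Scaffolders that count links over whole contigs therefore lose
discriminative power precisely when contigs get large: a 50-Mb contig
accumulates enough background (trans and long-range cis) links that
non-adjacent pairs start to rival adjacent ones. `hicend` inverts the
trade-off by counting links only inside small *end windows* — the first
(head) and last (tail) `w` bins of each contig, with 100-kb bins and `w`
between 5 and 25 bins by default.

The pipeline, per parameter combination, is:

1. **End-contact table.** For every pair of ends of different contigs, sum
   the matrix entries over the window bin pairs
   (`make_end_windows()`, `compute_end_contacts()`). Only contigs with at
   least `2w` bins get windows; smaller contigs are set aside and later
   attached by total links (`assign_small_contigs()`), without ordering.
2. **Turning point.** Sort the nonzero end-pair values in descending order,
   min-max normalize rank and value to the unit square, rotate the curve 45
   degrees anticlockwise and take the lowest point
   (`find_turning_point()`); on the normalized descending curve this is
   exactly `argmin(x + y)`. The knee value `T` separates the few large
   adjacent-pair (signal) values from the background (noise) bulk, and the
   usable cutoffs are multiples of it (`derive_cutoffs()`).
3. **Graph cleaning.** Contig ends are nodes, sister edges tie the two ends
   of one contig, and link edges join cross-contig end pairs whose contact
   strictly exceeds the cutoff (`build_link_graph()`). An edge survives
   `reciprocal_best_filter()` only when it is the unique maximum at both of
   its endpoints; `break_cycles()` then removes the weakest link of any
   remaining circular path (a chromosome whose two telomeric ends attract
   each other). What remains is a union of simple paths.
4. **Clusters.** Each path is an ordered, oriented contig list
   (`extract_clusters()`): a link leaving a tail or entering a head marks a
   contig forward; the mirror cases mark it reverse. A cluster and its
   reversal are the same object; `canonicalize_cluster()` fixes the
   representation.

## Consensus and robustness

A single parameter combination can be unlucky, so `scaffold_once()` runs the
whole grid — end sizes 0.5–2.5 Mb in 0.5-Mb steps, cutoff multipliers 1–5 in
0.5 steps, raw and normalized matrices: 5 × 9 × 2 = 90 cells — and
`merge_cluster_results()` counts how often each canonical cluster unit
recurs. Units are emitted greedily by frequency (ties: longer first, then
lexicographic), skipping any unit that reuses an already-placed contig;
leftover contigs fall back to singletons. The emitted frequency is the
cluster's *robustness*, at most 90 for the default grid; units at or near
the maximum are reproduced by essentially every parameter choice. The
turning point is computed independently per (end size, flavor) pair, so the
90 cutoffs derive from 10 knees.

Ties at the reciprocal-best maximum drop all tied edges rather than picking
one arbitrarily: a missed join costs a second round, a wrong join costs a
chromosome. The cutoff comparison is strict (`>`), matching the definition
of the knee as the last value of the signal regime. Contigs with exactly
`2w` bins are included (their windows touch but do not overlap); a `strict`
flag excludes them.

## Iterative rounds

When contig ends are repeat-rich, their mappable link density collapses and
round 1 (end sizes ≤ 2.5 Mb) cannot see across some junctions.
`run_iterative()` feeds each round's clusters back as super-contigs
(`build_super_assembly()` permutes bin order along the path, reversing
reverse-oriented members; bin ids — and hence the matrix — are untouched)
and raises the end sizes by 2.5 Mb per round (3–5 Mb, 5.5–7.5 Mb, 8–10 Mb).
Because super-contig end windows span member junctions, a 3–5-Mb window
reaches past a 2.5-Mb dead zone into informative sequence. Accuracy decays
with window size, so more than three rounds is refused by
`round_end_sizes()` without explicit override; when the chromosome number is
known, `target_n` stops the iteration as soon as it is reached, and the
iteration also stops when the cluster count stops decreasing.

## Mis-join detection

Assembly errors concatenate non-adjacent genomic segments, so the
intra-contig contact between bins 500 kb apart (5 bins at the default gap)
collapses at the junction. A breakpoint is called where this profile drops
below 10% of the genome-wide median for the same gap
(`detect_misjoins()`); since correctly assembled regions can also be
link-poor, a supplied unitig-to-contig map (`parse_unitig_map()` for
hifiasm-style GFA pairs, `read_unitig_map()` for the TSV form) restricts
calls to positions with a unitig boundary within one bin — mis-joins arise
from graph-cleaning mistakes and therefore fall on unitig boundaries.
Within a low-contact run the breakpoint goes to the bin boundary nearest
the minimum; among tied minima (common, because trough counts are
zero-inflated Poisson) the point nearest the run centre is used, which
centres the call on the junction. `apply_breaks()` splits bins and
sequences exactly; bin ids are stable so matrices never need recounting.
Raw counts, not normalized values, feed the profiles: balancing rescales
exactly the depleted rows whose depletion is the signal.

## The synthetic fixture generator

`simulate_assembly()` emulates the inputs the method assumes: chromosomes
are tiled into 100-kb bins; same-chromosome bin pairs at distance `d` bins
draw `Poisson(C * d^-alpha)` contacts with `alpha = 1` (the canonical Hi-C
decay) and `C = 100` at distance 1 (deep but routine coverage); different
chromosomes draw `Poisson(C/1000)` per bin pair. Chromosomes are fragmented
at uniformly sampled bin boundaries (stars-and-bars over the surplus bins,
so the minimum contig size is exact) into 1–6 contigs by default, matching
a near-chromosome HiFi assembly; contig names and bin numbering are
shuffled so adjacency is never encoded in ids, and orientation recovery is
exercised even though all true orientations are forward. The normalized
flavor is a single row-balancing pass — sufficient because the algorithm
consumes either flavor generically, and full iterative balancing would add
nothing the method reacts to. `inject_misjoins()` concatenates whole
contigs from different chromosomes, so the junction trough is at the trans
level; `mask_bins()` zeroes all contacts of chosen bins to emulate
unmappable repeat blocks at contig ends.

What the generator does *not* emulate: restriction-site granularity,
coverage waves, structural heterozygosity, and repeat-driven spurious
long-range cis enrichment. Passing the desk-scale checks therefore shows
the algorithm is implemented correctly under its own model, not that every
real genome will scaffold cleanly.

## Validation conditions and problem sizes

The recovery check runs twenty fixtures of 5 chromosomes (40/35/30/30/25
Mb) with 3–6 contigs each and a 5-Mb minimum contig size, chosen so that
every contig clears twice the largest default end window (2 × 2.5 Mb).
This mirrors the method's intended input regime — assemblies with N50 near
or over 10 Mb, a handful of contigs per chromosome — and the package
refuses nothing outside it: with contigs between 1 and 5 Mb, cells with
large windows exclude them, partial cluster units can out-vote the full
chromosome in the consensus, and those contigs end as robust singletons to
be attached by `assign_small_contigs()`. That behavior is inherent to
window-based eligibility, not an implementation artifact, and is why the
minimum-contig default of the generator (1 Mb) sits below the validation
fixture's 5 Mb.

The repeat-suppression check uses 3 chromosomes × 3 contigs of 30 Mb with
`C = 1000` and one junction per chromosome masked over 2.5 Mb on each side
— the smallest mask that defeats every round-1 window — and expects 6
clusters after round 1 and 3 after round 2. Mis-join detection runs on a
32-chromosome, 10-Mb-per-chromosome genome yielding 50 erroneous and ≥ 50
clean contigs. These sizes keep the full suite under a minute of compute
while leaving every rate estimated from at least 20 independent draws.

## Numerical choices and degenerate inputs

* Knee detection requires at least three nonzero values that are not all
  equal; otherwise it aborts with advice to set the cutoff manually, and a
  grid cell whose knee fails degrades to an empty result rather than
  poisoning the consensus.
* All ordering (canonical forms, tie-breaks, output order) uses byte-wise
  string comparison, never locale collation, so outputs are byte-identical
  across machines.
* Zeros are excluded from the ranked value vector: HiC-Pro matrices are
  sparse and the zero mass is an artifact of materialization, not a
  contact level.
* An even-length median is the mean of the central pair throughout.
* AGP gaps default to 100 bp (`U` records, `proximity_ligation` evidence),
  the conventional size for unsized proximity-ligation gaps.

## Limitations

Ordering and orientation of sub-window contigs is out of scope by design;
use a dedicated small-contig optimizer downstream. The method assumes the
contact matrices come from HiC-Pro at a fixed bin size — bin-size inference
and ICE normalization itself are not reimplemented. Robustness measures
stability across the parameter grid, not probability of correctness: a
systematic bias (e.g. a strong translocation signal) can be stable and
wrong in all 90 cells.
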