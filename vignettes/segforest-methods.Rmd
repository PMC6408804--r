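---
title: "Joint overlap of n interval sets with segment tree forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint overlap of n interval sets with segment tree forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segforest)
```

## The problem

Given n sets of genomic intervals in BED format, segforest reports every
region covered by at least one interval from *each* of the n sets — the
joint overlap — together with the tuple of source intervals that produced
it. No constraints are placed on the inputs: intervals within one set may
be unsorted, duplicated, nested, or mutually overlapping, which is
exactly the situation in which simpler sweep-based intersection tools
need pre-sorting or reject nested features.

Two search engines answer the pairwise sub-problems: a classical segment
tree with canonical subsets, and an indexed segment tree forest (ISTF)
derived from it. The two are equivalent by construction — every query
returns the identical result set — and the test suite asserts that
equivalence exhaustively.

## Coordinates

BED records are 0-based half-open. Internally every interval is the
inclusive integer range `[low, high] = [start, end - 1]`, and "overlap"
means at least one shared base. Records with `end <= start` denote empty
intervals; they are dropped on input and counted, not treated as errors.
Chromosome names are opaque strings compared exactly. On output, regions
are back-converted (`start = low`, `end = high + 1`).

## The segment tree

For one chromosome's intervals with distinct sorted endpoints
$p_1 < \dots < p_m$, the *elementary intervals* are, left to right,
$[p_1:p_1], (p_1:p_2), [p_2:p_2], \dots, [p_m:p_m]$. Because genomic
coordinates are integers, the open interval $(p_i : p_{i+1})$ is stored
as the integer range $[p_i + 1, p_{i+1} - 1]$ and omitted when empty.
The resulting leaves are pairwise disjoint, consecutive, and cover
$[p_1, p_m]$ exactly.

A balanced binary tree is built bottom-up over these leaves: consecutive
nodes are paired left to right, and a leftover node at any level is
promoted unchanged to the next level. This keeps the leaves in
coordinate order at every depth (a natural binning) and bounds the
height by $\lceil \log_2 L \rceil + 1$ for $L$ leaves.

Each node $\nu$ covers $Int(\nu)$, the union of its children's ranges.
An input interval $g$ is inserted from the root: if
$Int(\nu) \subseteq g$, $g$ joins the node's *canonical subset*
$I(\nu)$ and the descent stops on that branch; otherwise the insertion
recurses into each child overlapping $g$. Consequently every
$g \in I(\nu)$ contains $Int(\nu)$ but not $Int(parent(\nu))$, each
interval occupies at most two nodes per depth level, and total storage
is $O(n \log n)$. Canonical subsets preserve input order, making all
downstream output deterministic.

A stabbing query walks one root-to-leaf path (at most height + 1 nodes)
and emits the canonical subsets along it. An interval query — the
operation the n-way combiner actually uses — descends into every child
overlapping the query and emits $I(\nu)$ at each visited node; this is
sound because each $g \in I(\nu)$ contains $Int(\nu)$, so overlap of
the query with the node span implies overlap with $g$. Because an
interval may be attached at several visited nodes, hits are
deduplicated by uid. The traversal rule itself is fixed by the
requirement that the result equal a brute-force scan, which the tests
assert on randomized inputs.

## The indexed segment tree forest

On real data, attachments concentrate near the bottom of the tree, so
the top of the tree is mostly routing. The forest conversion removes it.

**Cut-off depth.** Let $d$ be the smallest root-relative depth at which
the cumulative attachments at depths $0..d$ exceed
`percentage`/100 of the total attachments $\sum_\nu |I(\nu)|$; the tree
is cut at depth $d + 1$, clamped to the tree height. "Total stored"
counts *attachments* (an interval stored at three nodes counts three),
which is the literal sum the rule refers to; counting distinct intervals
instead would move the cut by very little. Raising the percentage cuts
deeper (closer to the leaves) and relocates more intervals — the tested
monotonicity. The default percentage is 0.5.

**Forest membership.** The forest keeps the nodes at the cut-off depth
plus the childless nodes above it, in left-to-right coordinate order.
These members partition $[p_1, p_m]$, and are doubly linked in that
order (the linked nodes).

**Moving intervals.** Every attachment above the cut-off sitting at an
internal node $v$ is re-attached to *every* forest member inside $v$'s
subtree. When all of $v$'s relevant descendants sit at the cut-off
depth this is precisely "attach to the offspring at the cut-off depth";
when $v$'s subtree bottoms out above the cut-off it reduces to the
childless-node cases (the node itself if it has no offspring, its
lowest offspring otherwise). The general rule also covers mixed
subtrees that contain both kinds of member — attaching only to
cut-off-depth offspring would lose coverage over the childless leaves'
spans — and is forced by the query-equivalence contract. Donor nodes
are processed shallowest-first, ties left to right, to keep receiving
lists deterministic. A relocated interval contains the whole span of
each receiving member, so the member's short tree emits it whenever a
query touches that member at all. `forestStats()` reports both the
number of source attachments moved and the number of placed copies.

**Hash index.** Each member is indexed by
$\mathrm{hashIndex} = \lfloor low / \mathrm{preset} \rfloor$. Members
sharing an index (a contiguous run, since member starts increase) form
one *collision BST*, built balanced in one shot from the sorted run:
members sit at the leaf positions, artificial routing nodes above them.
A single member has height 1 by convention, and a run of $k$ members
has height $\lceil \log_2 k \rceil + 1$; the explicit structure is
available through `bucketBST()`. Because the same balanced shape would
be rebuilt from any run, a bucket's BST can never be taller than the
original segment tree on the same data — the property the tests check
over the whole percentage grid. The default preset of 1,000,000 bp
gives at most a few hundred buckets per chromosome on human-scale
coordinates; smaller presets mean more, smaller buckets (also tested as
a monotone trend).

**Query.** For a query $[q_l, q_h]$, compute
$\mathrm{lowIndex} = \lfloor q_l/\mathrm{preset}\rfloor$ and
$\mathrm{highIndex} = \lfloor q_h/\mathrm{preset}\rfloor$, then resolve
a starting member through a cascade: the lowIndex bucket if occupied
(rightmost member with $low \le q_l$, else the bucket's leftmost);
otherwise the highest occupied index below it; otherwise the highIndex
bucket; otherwise the lowest occupied index above it. One completion
was added to the published cascade: when the query strictly spans past
*both* ends of the occupied index range (no bucket at or below
lowIndex, none at or above highIndex), the four steps all fail even
though interior buckets overlap the query, so a final fallback starts
at the highest occupied index below highIndex. From the start, the walk
slides along the linked list to the contiguous run of members
overlapping the query and runs each member's short-tree query. Since
consecutive members are coordinate-adjacent, at most one member outside
the `[lowIndex, highIndex]` bucket range is touched on each side — at
most two extra index searches per query, which the instrumented tests
(`extraNodes` attribute) bound explicitly.

## n-way combination

The set list is split recursively at its midpoint. A single set is
echoed as unit records; a pair — and every combine of two intermediate
results — builds the engine on the *smaller* side (bounding build cost
and memory) and queries it with the larger. Each overlapping pair
$(a, b)$ yields one record spanning
$[\max(a_{low}, b_{low}), \min(a_{high}, b_{high})]$ whose contributor
tuple concatenates both sides' tuples, left side first.

Intermediate results are intersection *regions*, not original
intervals: regions make the combine associative, so any split order
yields the same final multiset (asserted by comparing the midpoint
recursion against a left fold). Records are kept per contributing
tuple, with duplicates retained — this multiset convention is what
makes the counts identical to per-pair `bedtools intersect` counts,
which the tests verify directly against the installed bedtools.

Chromosomes are processed independently (a chromosome missing from any
one set cannot contribute) and concatenated in sorted chromosome order;
within a chromosome, records are sorted by (low, high, contributor
uids). The `workers` argument forks per-chromosome jobs; the contract
is determinism — the output is identical for any worker count — not a
particular scheduling.

## Parameters

| parameter    | default   | units | meaning                                        |
|--------------|-----------|-------|------------------------------------------------|
| `percentage` | 0.5       | % of attachments | cut-off rule threshold; higher cuts deeper and moves more intervals |
| `preset`     | 1,000,000 | bp    | hash divisor; smaller values mean more, smaller buckets |
| `workers`    | 1         | —     | forked per-chromosome jobs; output-invariant   |
| `method`     | `"st"`    | —     | `"st"` or `"istf"`; equivalent results         |

## The synthetic generator and what the tests show

`generateUniformSets()` reproduces the semi-synthetic study conditions:
fixed-length intervals (500 bp by default) with chromosomes drawn
proportionally to length and starts uniform in
`[0, length - intervalLen]`, over 24 hg19-scale chromosomes (a static
table; any `chrom.sizes` file can replace it). Seeds are mandatory and
a single stream drives all files, so generation is byte-reproducible.
Under these conditions the joint overlap of 8 or more files of 100,000
intervals is zero with overwhelming probability — the structurally
forced count the acceptance checks reproduce — while 2-file counts grow
roughly quadratically in the per-file interval count.

The generator emulates density and length scale, not biology: real
peak sets cluster in hotspots, have variable lengths, and correlate
across assays. Passing tests therefore demonstrate correctness of the
interval arithmetic and data structures on inputs at least as
adversarial as real data (the adversarial generator covers nesting,
duplication, shared endpoints, adjacency, point intervals and unsorted
order), but say nothing about biological enrichment. Uniform sampling
details (per-chromosome weighting, boundary handling) are declared
choices; published counts that depend on an unspecified sampler are
accordingly not reproduction targets, only the structural zeros are.

Verification sizes are a deliberate trade-off: 100 randomized fixtures
of 2–16 sets with up to 2,000 intervals each for the three-way
engine/oracle equivalence, and single runs at the 100,000-interval
scale for the byte-identity, zero-count and BST-height properties.

## Numerical and degenerate-input conventions

* Open elementary intervals are integerised and dropped when empty.
* A leftover node during bottom-up pairing is promoted unchanged.
* BST height: a single node has height 1, everywhere.
* Depth is root-relative (root = 0); the cut-off is clamped to the
  height, so `percentage = 100` cuts at the leaves.
* Empty inputs: an empty BED file is an empty set, an empty set gives
  an empty tree/forest, and queries on them return empty results; a
  one-leaf tree has height 0 and cut-off 0 (the root is the forest).
* uids are `"s<set>.<i>"` tokens, unique per run; all result ordering
  falls back to uid order for ties.

## Known limitations

* Inputs are memory-resident; there is no streaming or tabix path.
* Counts are per contributing tuple — deliberately *not* merged
  regions, so they match pairwise `bedtools intersect`, not
  `multiinter` column semantics.
* No strand awareness, minimum-overlap fractions, or BAM/GFF/VCF input.
* Forests are static: no insertion or deletion after construction.
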