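# segforest

Joint overlap analysis of *n* genomic interval sets: given BED files,
segforest reports every region covered by at least one interval from
**each** input set, together with the tuple of source intervals that
produced it. Inputs need no preparation — intervals within a set may be
unsorted, duplicated, nested or overlapping, the cases in which
sort-based intersection tools need preprocessing or refuse nested
features. Typical users are epigenomics / regulatory-genomics analysts
intersecting many peak or hotspot tracks (DNase hypersensitivity,
histone marks, TF binding) at once.

## Method

The n-way problem is reduced to pairwise intersections by divide and
conquer: the set list is split recursively at the midpoint, a single set
is echoed, and each combine builds a search index on the smaller side
and queries it with the larger. Intermediate results are intersection
regions, which makes the combine associative and the output independent
of the split and of the per-chromosome parallelism.

Two equivalent engines answer the pairwise step:

* **Segment tree (ST).** For endpoints p₁ < … < p_m the elementary
  intervals [p₁:p₁], (p₁:p₂), …, [p_m:p_m] become the leaves of a
  balanced tree built bottom-up. Node ν covers Int(ν); interval g joins
  the canonical subset I(ν) of the highest nodes with Int(ν) ⊆ g, so
  each interval occupies ≤ 2 nodes per level and storage is O(n log n).
  A stabbing query walks one root-to-leaf path; an interval query
  descends into every overlapping child and deduplicates by uid.
* **Indexed segment tree forest (ISTF).** The tree is cut at the
  smallest depth d where the attachments accumulated from the root
  exceed `percentage`% (default 0.5) of all attachments, plus one. The
  nodes at the cut plus childless nodes above it survive as a forest,
  doubly linked in coordinate order; attachments stranded above the cut
  are relocated to the members of their subtree. Each member is hashed
  by ⌊low / preset⌋ (default preset 10⁶ bp) and same-index members form
  a balanced collision BST whose height never exceeds the source tree's.
  A query resolves its start bucket via the lowIndex / lowerIndex /
  highIndex / higherIndex cascade and touches at most two members
  outside the [lowIndex, highIndex] bucket range.

One record is emitted per contributing tuple (multiset semantics), which
makes counts identical to pairwise `bedtools intersect` counts — an
identity the test suite checks directly.

## Worked example

```r
library(segforest)
sets <- generateUniformSets(3, 50000, 500L, seed = 7)  # 3 files, 50k x 500 bp
res <- jointOverlap(sets, method = "istf")
res
#> OverlapRecords: 12 region(s) from 3 input set(s)
head(as.data.frame(res), 3)
#>   chrom      low     high     uid1     uid2     uid3
#> 1  chr1  1235675  1235976 s1.36954 s2.16694 s3.49659
#> 2 chr10 55694400 55694498 s1.16950  s2.3471   s3.572
#> 3 chr14 73114560 73114908   s1.688 s2.45830 s3.48242
countOverlapRecords(res)
#> [1] 12
```

Twelve regions of the ~3.1 Gb model genome are hit by all three 50,000
interval sets; each row names the region (inclusive internal
coordinates) and the one source interval per set (`uid1`–`uid3`) whose
intersection it is. `writeOverlaps(res, "out.bed")` back-converts to
half-open BED.

The structures themselves are inspectable:

```r
tree <- buildSegmentTree(sets[[1]], chrom = "chr21")
tree
#> SegmentTree on chr21: 809 interval(s), 3235 leaves, height 12, 1621 attachment(s)
forest <- buildForest(tree)   # percentage 0.5, preset 1e6
forest
#> IndexedForest on chr21: 483 forest node(s) in 49 bucket(s), cut-off depth 9, preset 1000000
forestStats(forest)$meanBstHeight   # 4.55, below the tree height of 12
```

A command-line wrapper with `intersect`, `generate` and `stats`
subcommands is installed at
`system.file("scripts", "segforest.R", package = "segforest")`:

```sh
Rscript segforest.R generate --n-files=4 --n-intervals=100000 --seed=1 --output=data/
Rscript segforest.R intersect --method=istf --output=joint.bed data/uniform_*.bed
```

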