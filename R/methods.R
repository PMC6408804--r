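## Accessors and show methods.

#' @describeIn IntervalSet index of the source set
#' @param x an object
#' @export
setMethod("setId", "IntervalSet", function(x) x@setId)

#' @describeIn IntervalSet number of intervals
#' @export
setMethod("nIntervals", "IntervalSet", function(x) nrow(x@data))

#' @describeIn IntervalSet chromosomes present, in order of appearance
#' @export
setMethod("chromNames", "IntervalSet", function(x) unique(x@data$chrom))

#' @describeIn IntervalSet named list of per-chromosome data.frames
#'   (input order preserved within each chromosome)
#' @export
setMethod("chromPartition", "IntervalSet", function(x) {
  split(x@data, factor(x@data$chrom, levels = unique(x@data$chrom)))
})

#' @describeIn IntervalSet number of empty BED records dropped on input
#' @export
setMethod("droppedRecords", "IntervalSet", function(x) x@dropped)

#' @export
setMethod("length", "IntervalSet", function(x) nrow(x@data))

setMethod("show", "IntervalSet", function(object) {
  cat(sprintf("IntervalSet (set %d): %d interval(s) on %d chromosome(s)\n",
              object@setId, nrow(object@data),
              length(unique(object@data$chrom))))
  if (object@dropped > 0L)
    cat(sprintf("  %d empty record(s) dropped on input\n", object@dropped))
})

#' @export
setMethod("as.data.frame", "IntervalSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

#' @describeIn SegmentTree chromosome the tree was built for
#' @param x an object
#' @export
setMethod("chromNames", "SegmentTree", function(x) x@chrom)

#' @describeIn SegmentTree maximum leaf depth (root = depth 0)
#' @export
setMethod("treeHeight", "SegmentTree", function(x) x@index$height)

#' @describeIn SegmentTree number of elementary-interval leaves
#' @export
setMethod("nLeaves", "SegmentTree", function(x) x@index$n_leaves)

#' @describeIn SegmentTree total attachments, sum over nodes of |I(v)|
#' @export
setMethod("nStored", "SegmentTree", function(x) x@index$n_stored)

#' @describeIn SegmentTree number of stored input intervals
#' @export
setMethod("nIntervals", "SegmentTree", function(x) nrow(x@intervals))

setMethod("show", "SegmentTree", function(object) {
  cat(sprintf(paste0("SegmentTree on %s: %d interval(s), %d leaves, ",
                     "height %d, %d attachment(s)\n"),
              object@chrom, nrow(object@intervals), object@index$n_leaves,
              object@index$height, object@index$n_stored))
})

#' @describeIn IndexedForest cut-off depth used (root-relative)
#' @param x an object
#' @export
setMethod("cutoffDepth", "IndexedForest", function(x) x@forest$cutoff)

#' @describeIn IndexedForest hash divisor in bp
#' @export
setMethod("presetValue", "IndexedForest", function(x) x@preset)

#' @describeIn IndexedForest number of retained (linked) forest nodes
#' @export
setMethod("nForestNodes", "IndexedForest", function(x) length(x@forest$members))

#' @describeIn IndexedForest number of occupied hash indexes
#' @export
setMethod("bucketCount", "IndexedForest", function(x) length(x@forest$bucket_idx))

#' @describeIn IndexedForest the source segment tree
#' @export
setMethod("sourceTree", "IndexedForest", function(x) x@tree)

#' @describeIn IndexedForest chromosome of the source tree
#' @export
setMethod("chromNames", "IndexedForest", function(x) x@tree@chrom)

setMethod("show", "IndexedForest", function(object) {
  cat(sprintf(paste0("IndexedForest on %s: %d forest node(s) in %d ",
                     "bucket(s), cut-off depth %d, preset %d\n"),
              object@tree@chrom, length(object@forest$members),
              length(object@forest$bucket_idx), object@forest$cutoff,
              object@preset))
})

#' @describeIn GenomeModel named chromosome lengths (bp)
#' @param x an object
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@sizes)

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosome(s), %.0f bp total\n",
              length(object@sizes), sum(object@sizes)))
})

#' @export
setMethod("length", "OverlapRecords", function(x) length(x@low))

#' @describeIn OverlapRecords character matrix of contributing uids
#' @param x an object
#' @export
setMethod("contributorMatrix", "OverlapRecords", function(x) x@contributors)

#' @export
setMethod("as.data.frame", "OverlapRecords",
          function(x, row.names = NULL, optional = FALSE, ...) {
  d <- data.frame(chrom = x@chrom, low = x@low, high = x@high,
                  stringsAsFactors = FALSE)
  k <- ncol(x@contributors)
  if (k > 0 && nrow(d) > 0) {
    for (j in seq_len(k)) d[[sprintf("uid%d", j)]] <- x@contributors[, j]
  }
  d
})

setMethod("show", "OverlapRecords", function(object) {
  cat(sprintf("OverlapRecords: %d region(s) from %d input set(s)\n",
              length(object@low), ncol(object@contributors)))
})

#' Number of jointly overlapping records
#'
#' The reported overlap statistic: the number of contributing tuples, with
#' no merging or deduplication beyond record construction.
#'
#' @param records an [OverlapRecords-class] object.
#' @return integer count.
#' @export
countOverlapRecords <- function(records) {
  stopifnot(is(records, "OverlapRecords"))
  length(records@low)
}
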