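## Central S4 containers. Coordinates are always internal inclusive integers:
## a BED record [start, end) maps to [low, high] = [start, end - 1], so an
## overlap means at least one shared base.

#' IntervalSet: one input set of genomic intervals
#'
#' Holds one interval set in input order. Intervals may be unsorted,
#' duplicated, nested or overlapping; no normalisation beyond the BED
#' half-open to inclusive coordinate conversion is applied.
#'
#' @slot setId integer index of the source set (>= 1).
#' @slot data data.frame with columns `chrom` (character), `low`, `high`
#'   (inclusive integer coordinates) and `uid` (character, unique per run).
#' @slot dropped number of empty (end <= start) BED records discarded on
#'   input.
#' @export
setClass("IntervalSet",
         representation(setId = "integer", data = "data.frame",
                        dropped = "integer"))

setValidity("IntervalSet", function(object) {
  d <- object@data
  need <- c("chrom", "low", "high", "uid")
  if (!all(need %in% names(d)))
    return(sprintf("data must have columns %s", paste(need, collapse = ", ")))
  if (length(object@setId) != 1L || is.na(object@setId) || object@setId < 0L)
    return("setId must be a single non-negative integer")
  if (nrow(d)) {
    if (any(d$low > d$high)) return("low > high")
    if (any(!nzchar(d$chrom) | is.na(d$chrom)))
      return("chromosome names must be non-empty")
    if (anyDuplicated(d$uid)) return("uids must be unique")
  }
  TRUE
})

#' Construct an IntervalSet from inclusive coordinates
#'
#' @param chrom character vector of chromosome names (compared exactly; no
#'   "chr" normalisation).
#' @param low,high inclusive integer coordinates, `low <= high`.
#' @param setId integer index of the source set.
#' @param uid optional character uids; defaults to `"s<setId>.<i>"`.
#' @param dropped count of input records discarded before construction.
#' @return An [IntervalSet-class] object.
#' @examples
#' IntervalSet(c("chr1", "chr1"), c(10L, 5L), c(19L, 7L))
#' @export
IntervalSet <- function(chrom, low, high, setId = 1L, uid = NULL,
                        dropped = 0L) {
  n <- length(low)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(uid)) uid <- if (n) sprintf("s%d.%d", setId, seq_len(n)) else character(0)
  d <- data.frame(chrom = as.character(chrom), low = as.integer(low),
                  high = as.integer(high), uid = as.character(uid),
                  stringsAsFactors = FALSE)
  new("IntervalSet", setId = as.integer(setId), data = d,
      dropped = as.integer(dropped))
}

#' SegmentTree: per-chromosome segment tree with canonical subsets
#'
#' A balanced binary tree over the elementary intervals induced by the
#' distinct endpoints of one chromosome's intervals. Each node v covers an
#' inclusive range Int(v); its canonical subset I(v) holds the input
#' intervals that fully contain Int(v) but not Int(parent(v)).
#'
#' @slot chrom chromosome the tree was built for.
#' @slot intervals data.frame (`low`, `high`, `uid`) of the stored
#'   intervals, in input order; canonical subsets reference its rows.
#' @slot index flat tree representation (node coordinate, child, depth and
#'   canonical-subset arrays) produced by the compiled builder.
#' @export
setClass("SegmentTree",
         representation(chrom = "character", intervals = "data.frame",
                        index = "list"))

#' IndexedForest: hash-indexed forest of short segment trees
#'
#' Obtained by cutting a [SegmentTree-class] at a data-driven cut-off depth.
#' The forest keeps the nodes at the cut-off depth plus childless nodes
#' above it, in left-to-right coordinate order (the doubly linked node
#' list); each retained node is hashed by `floor(low / preset)` and nodes
#' sharing an index form a balanced collision BST.
#'
#' @slot tree the source [SegmentTree-class].
#' @slot percentage cut-off percentage parameter (percent of total stored
#'   attachments).
#' @slot preset hash divisor in base pairs.
#' @slot forest flat forest representation (member nodes, hash indexes,
#'   bucket runs, relocated attachments) produced by the compiled builder.
#' @export
setClass("IndexedForest",
         representation(tree = "SegmentTree", percentage = "numeric",
                        preset = "integer", forest = "list"))

#' GenomeModel: chromosome names and lengths
#'
#' @slot sizes named numeric vector of chromosome lengths in bp.
#' @export
setClass("GenomeModel", representation(sizes = "numeric"))

setValidity("GenomeModel", function(object) {
  s <- object@sizes
  if (!length(s)) return("at least one chromosome required")
  if (is.null(names(s)) || any(!nzchar(names(s))))
    return("chromosome lengths must be named")
  if (any(!is.finite(s) | s <= 0)) return("all lengths must be > 0")
  TRUE
})

#' GenomeModel constructor
#'
#' @param sizes named numeric vector of chromosome lengths (bp).
#' @return A [GenomeModel-class].
#' @export
GenomeModel <- function(sizes) new("GenomeModel", sizes = sizes)

#' OverlapRecords: jointly overlapping regions with provenance
#'
#' One row per contributing tuple: for an n-set run each record is the
#' intersection of exactly one interval from every input set, and
#' `contributors` holds that tuple of source uids (one column per set).
#' Duplicate tuples producing identical regions are retained (multiset
#' semantics, matching per-pair intersection counts).
#'
#' @slot chrom,low,high region coordinates (inclusive integers).
#' @slot contributors character matrix, one column per input set.
#' @export
setClass("OverlapRecords",
         representation(chrom = "character", low = "integer",
                        high = "integer", contributors = "matrix"))

setValidity("OverlapRecords", function(object) {
  n <- length(object@low)
  if (length(object@chrom) != n || length(object@high) != n)
    return("chrom, low, high must have equal length")
  if (nrow(object@contributors) != n)
    return("contributors must have one row per record")
  if (n && any(object@low > object@high)) return("low > high")
  TRUE
})

#' OverlapRecords constructor
#'
#' @param chrom,low,high region coordinates (inclusive integers).
#' @param contributors character matrix of source uids, one row per record
#'   and one column per contributing input set.
#' @return An [OverlapRecords-class].
#' @export
OverlapRecords <- function(chrom = character(0), low = integer(0),
                           high = integer(0),
                           contributors = matrix(character(0),
                                                 nrow = length(low))) {
  new("OverlapRecords", chrom = as.character(chrom), low = as.integer(low),
      high = as.integer(high), contributors = contributors)
}
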