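## Segment tree construction and queries. The real-line formulation is
## integerised: the open elementary interval (p_i, p_{i+1}) becomes the
## integer range [p_i + 1, p_{i+1} - 1] and is omitted when empty, so the
## leaves are pairwise disjoint, consecutive, and cover [p_1, p_m] exactly.

#' Elementary partition of a set of intervals
#'
#' Computes the sorted distinct endpoints p_1..p_m of the given inclusive
#' intervals and the elementary intervals they induce: a single-point leaf
#' `[p_i, p_i]` for every endpoint and, between consecutive endpoints, the
#' gap leaf `[p_i + 1, p_{i+1} - 1]` whenever it is non-empty.
#'
#' @param low,high inclusive integer coordinates of intervals on one
#'   chromosome; must be non-empty.
#' @return list with `endpoints` (increasing integer vector) and `leaves`
#'   (data.frame `low`, `high`, in left-to-right order).
#' @examples
#' elementaryPartition(c(2L, 5L), c(5L, 9L))
#' @export
elementaryPartition <- function(low, high) {
  if (!length(low)) stop("empty input: no elementary partition")
  stopifnot(length(low) == length(high), all(low <= high))
  p <- sort(unique(c(as.integer(low), as.integer(high))))
  gap <- which(diff(p) > 1L)
  llow <- sort(c(p, p[gap] + 1L))
  lhigh <- sort(c(p, p[gap + 1L] - 1L))
  list(endpoints = p,
       leaves = data.frame(low = llow, high = lhigh))
}

#' Build a segment tree for one chromosome
#'
#' Builds a balanced binary tree bottom-up over the elementary-interval
#' leaves (consecutive leaves paired left to right; a leftover node is
#' promoted unchanged to the next level), then inserts every input
#' interval from the root: an interval is attached to the canonical subset
#' of the highest nodes whose span it fully contains, descending into each
#' overlapping child otherwise. Canonical subsets preserve input order.
#'
#' @param x an [IntervalSet-class] (restricted to `chrom` if given, which
#'   is required when the set spans several chromosomes), or a data.frame
#'   with columns `low`, `high`, `uid`.
#' @param chrom chromosome to build for.
#' @return A [SegmentTree-class]; an empty input yields an empty tree.
#' @examples
#' iv <- IntervalSet(c("chr1", "chr1"), c(2L, 5L), c(9L, 9L))
#' buildSegmentTree(iv)
#' @export
buildSegmentTree <- function(x, chrom = NULL) {
  if (is(x, "IntervalSet")) {
    d <- x@data
    if (is.null(chrom)) {
      cn <- unique(d$chrom)
      if (length(cn) > 1L)
        stop("set spans several chromosomes; pass `chrom`")
      chrom <- if (length(cn)) cn else NA_character_
    } else {
      d <- d[d$chrom == chrom, , drop = FALSE]
    }
  } else {
    d <- x
    if (is.null(chrom)) chrom <- NA_character_
  }
  idx <- .st_build(as.integer(d$low), as.integer(d$high))
  new("SegmentTree", chrom = as.character(chrom),
      intervals = data.frame(low = as.integer(d$low),
                             high = as.integer(d$high),
                             uid = as.character(d$uid),
                             stringsAsFactors = FALSE),
      index = idx)
}

.hits_to_df <- function(tree, ids) {
  ids <- sort(ids)  # input order, deterministic
  tree@intervals[ids, , drop = FALSE]
}

#' @describeIn SegmentTree stabbing query: all stored intervals containing
#'   the coordinate `at`, found on one root-to-leaf walk. The result
#'   carries the number of nodes visited as attribute `nodesVisited`.
#' @param at integer coordinate.
#' @export
setMethod("queryPoint", "SegmentTree", function(x, at) {
  stopifnot(length(at) == 1L)
  r <- .st_query_points(x@index, as.integer(at))
  out <- .hits_to_df(x, r$hits[[1L]])
  attr(out, "nodesVisited") <- r$visits[1L]
  out
})

#' @describeIn SegmentTree interval query: all stored intervals sharing at
#'   least one base with `[qlow, qhigh]`, each reported once (deduplicated
#'   by uid); multi-branch descent into every child overlapping the query.
#' @param qlow,qhigh inclusive query coordinates, `qlow <= qhigh`.
#' @export
setMethod("queryInterval", "SegmentTree", function(x, qlow, qhigh) {
  stopifnot(length(qlow) == 1L, length(qhigh) == 1L, qlow <= qhigh)
  r <- .st_query_intervals(x@index, as.integer(qlow), as.integer(qhigh))
  out <- .hits_to_df(x, r$iid)
  attr(out, "nodesVisited") <- r$visits[1L]
  out
})

#' @describeIn SegmentTree structure summary: `height`, `nLeaves`,
#'   `nStored` and the attachments-per-depth vector (named by depth from
#'   the root; sums to `nStored`).
#' @export
setMethod("treeStats", "SegmentTree", function(x) {
  idx <- x@index
  if (idx$root == 0L)
    return(list(height = 0L, nLeaves = 0L, nStored = 0L,
                attachmentsByDepth = integer(0)))
  counts <- diff(idx$canon_ptr)
  att <- vapply(0:idx$height, function(d) sum(counts[idx$depth == d]),
                integer(1))
  names(att) <- 0:idx$height
  list(height = idx$height, nLeaves = idx$n_leaves,
       nStored = idx$n_stored, attachmentsByDepth = att)
})

#' Structural validation of a segment tree
#'
#' Asserts, by direct inspection of the flat representation: child spans
#' are disjoint, consecutive and union to the parent span; every canonical
#' attachment fully contains its node's span but not the parent's span;
#' leaves are in strictly increasing coordinate order and partition
#' [p_1, p_m]; the height bound `height <= ceiling(log2(nLeaves)) + 1`;
#' and each interval is attached to at most two nodes per depth level.
#'
#' @param tree a [SegmentTree-class].
#' @return `TRUE` invisibly, or an error describing the violated property.
#' @export
validateSegmentTree <- function(tree) {
  idx <- tree@index
  if (idx$root == 0L) return(invisible(TRUE))
  lo <- idx$node_low; hi <- idx$node_high
  lc <- idx$left; rc <- idx$right
  internal <- which(lc != 0L)
  if (length(internal)) {
    if (any(lo[internal] != lo[lc[internal]]) ||
        any(hi[internal] != hi[rc[internal]]))
      stop("parent span != union of child spans")
    if (any(hi[lc[internal]] + 1L != lo[rc[internal]]))
      stop("children not disjoint-consecutive")
  }
  parent <- integer(length(lo))
  parent[lc[internal]] <- internal
  parent[rc[internal]] <- internal
  np <- diff(idx$canon_ptr)
  node_of <- rep.int(seq_along(np), np)
  g <- idx$canon_idx
  glow <- tree@intervals$low[g]; ghigh <- tree@intervals$high[g]
  if (any(glow > lo[node_of]) || any(ghigh < hi[node_of]))
    stop("canonical interval does not contain its node span")
  pa <- parent[node_of]
  haspa <- pa != 0L
  if (any(glow[haspa] <= lo[pa[haspa]] & ghigh[haspa] >= hi[pa[haspa]]))
    stop("canonical interval contains the parent span")
  leaves <- which(lc == 0L)
  leaves <- leaves[order(lo[leaves])]
  if (length(leaves) > 1L &&
      any(lo[leaves][-1L] != hi[leaves][-length(leaves)] + 1L))
    stop("leaves do not partition the span")
  if (idx$height > ceiling(log2(max(idx$n_leaves, 2L))) + 1L)
    stop("height bound violated")
  perlevel <- table(paste(g, idx$depth[node_of]))
  if (length(perlevel) && max(perlevel) > 2L)
    stop("an interval is attached to more than 2 nodes at one depth")
  invisible(TRUE)
}
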