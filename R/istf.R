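## Indexed segment tree forest: cut the tree at a data-driven depth, keep
## the nodes at that depth plus childless nodes above it (doubly linked in
## coordinate order), hash each retained node by floor(low / preset), and
## resolve hash collisions with balanced BSTs over the linked nodes.

#' Decide the cut-off depth
#'
#' Finds the smallest depth d (from the root) at which the cumulative
#' number of attachments stored at depths 0..d exceeds
#' `percentage`/100 of the total attachments in the tree, and returns
#' d + 1, clamped to the tree height when no such depth exists below it.
#'
#' @param tree a built, non-empty [SegmentTree-class].
#' @param percentage cut-off percentage in (0, 100]; default 0.5.
#' @return integer cut-off depth (root-relative).
#' @export
decideCutoffDepth <- function(tree, percentage = 0.5) {
  stopifnot(is(tree, "SegmentTree"))
  if (tree@index$root == 0L) stop("empty tree has no cut-off depth")
  if (!(percentage > 0 && percentage <= 100))
    stop("percentage must be in (0, 100]")
  st <- treeStats(tree)
  cum <- cumsum(st$attachmentsByDepth)
  d <- which(cum > percentage / 100 * st$nStored)[1L] - 1L
  if (is.na(d)) return(st$height)
  min(d + 1L, st$height)
}

#' Hash index of a start coordinate
#'
#' `hashIndex = floor(low / preset)`: the universal hash used to index the
#' forest's linked nodes by their start coordinate.
#'
#' @param low non-negative integer coordinate(s).
#' @param preset positive integer divisor in bp.
#' @return integer hash index(es).
#' @examples
#' hashIndex(2345678, 1000000)  # 2
#' @export
hashIndex <- function(low, preset) {
  if (length(preset) != 1L || is.na(preset) || preset <= 0)
    stop("preset must be a positive integer")
  if (any(low < 0)) stop("coordinates must be non-negative")
  as.integer(low %/% preset)
}

#' Convert a segment tree into an indexed segment tree forest
#'
#' Cuts `tree` at [decideCutoffDepth()]. The forest keeps the nodes at the
#' cut-off depth plus the childless nodes above it, in left-to-right
#' coordinate order. Every attachment stored above the cut-off at an
#' internal node is relocated to all forest members in that node's subtree
#' (relocation processes donor nodes shallowest-first, ties left to
#' right), so no interval is lost by cutting. Members are then hashed by
#' [hashIndex()]; members sharing an index form one balanced collision BST
#' (built in one shot from the sorted run; a single member has height 1,
#' artificial routing nodes sit above the members otherwise).
#'
#' @param tree a [SegmentTree-class].
#' @param percentage cut-off percentage in (0, 100]; default 0.5.
#' @param preset positive integer hash divisor in bp; default 1000000.
#' @return An [IndexedForest-class]; empty tree gives an empty forest.
#' @export
buildForest <- function(tree, percentage = 0.5, preset = 1000000L) {
  stopifnot(is(tree, "SegmentTree"))
  if (length(preset) != 1L || is.na(preset) || preset <= 0)
    stop("preset must be a positive integer")
  cutoff <- if (tree@index$root == 0L) 0L
            else decideCutoffDepth(tree, percentage)
  f <- .istf_build(tree@index, as.integer(cutoff), as.integer(preset))
  new("IndexedForest", tree = tree, percentage = as.numeric(percentage),
      preset = as.integer(preset), forest = f)
}

#' Resolve the starting linked node for a forest query
#'
#' Implements the index cascade: the bucket at
#' `lowIndex = floor(qlow / preset)` if occupied; else the highest
#' occupied index below it (`lowerIndex`); else the bucket at
#' `highIndex = floor(qhigh / preset)`; else the lowest occupied index
#' above it (`higherIndex`); else a final interior fallback (the highest
#' occupied index below `highIndex`, reached only when the query strictly
#' spans past both ends of the occupied index range). Within a bucket the
#' rightmost member with `low <= qlow` is chosen, else the bucket's
#' leftmost member. `branch == "none"` means no candidate exists and the
#' query overlaps nothing.
#'
#' @param forest an [IndexedForest-class].
#' @param qlow,qhigh inclusive query coordinates.
#' @return list with `pos` (member position in coordinate order, 0 if
#'   none), `node` (source-tree node id or `NA`), `interval` (member span
#'   or `NULL`) and `branch` (which cascade step resolved the start).
#' @export
lookupStart <- function(forest, qlow, qhigh) {
  stopifnot(is(forest, "IndexedForest"), qlow <= qhigh)
  r <- .istf_lookup(forest@forest, as.integer(qlow), as.integer(qhigh),
                    forest@preset)
  branches <- c("lowIndex", "lowerIndex", "highIndex", "higherIndex",
                "interiorFallback")
  list(pos = r$pos,
       node = if (r$pos) forest@forest$members[r$pos] else NA_integer_,
       interval = if (r$pos) c(forest@forest$member_low[r$pos],
                               forest@forest$member_high[r$pos]) else NULL,
       branch = if (r$branch) branches[r$branch] else "none")
}

#' Interval query on an indexed forest
#'
#' Starts at [lookupStart()]'s node, slides along the linked node list to
#' the contiguous run of members overlapping the query (at most one extra
#' node outside the `[lowIndex, highIndex]` bucket range on each side),
#' and runs the short-tree interval query on every member in the run,
#' including its relocated attachments. Results are deduplicated by uid
#' and are identical to [queryInterval()] on the source tree. Attributes
#' `extraNodes` (members visited outside the `[lowIndex, highIndex]`
#' bucket range) and `nodesVisited` instrument the walk.
#'
#' @param x an [IndexedForest-class].
#' @param qlow,qhigh inclusive query coordinates, `qlow <= qhigh`.
#' @return data.frame of matching intervals (`low`, `high`, `uid`).
#' @export
setMethod("queryInterval", "IndexedForest", function(x, qlow, qhigh) {
  stopifnot(length(qlow) == 1L, length(qhigh) == 1L, qlow <= qhigh)
  r <- .istf_query_intervals(x@tree@index, x@forest, as.integer(qlow),
                             as.integer(qhigh), x@preset)
  out <- .hits_to_df(x@tree, r$iid)
  attr(out, "extraNodes") <- r$extra[1L]
  attr(out, "nodesVisited") <- r$visits[1L]
  out
})

#' Explicit collision BST of one bucket
#'
#' Materialises the balanced binary search tree over the linked nodes of
#' bucket `b` (in-order = coordinate order): leaves hold forest members,
#' internal artificial nodes carry only a routing key (the largest member
#' start in their left subtree). A single member is a height-1 leaf.
#'
#' @param forest an [IndexedForest-class].
#' @param b bucket number (1-based, in increasing hash-index order).
#' @return nested list with fields `kind` ("member"/"artificial"),
#'   `height` and, for artificial nodes, `key`, `left`, `right`.
#' @export
bucketBST <- function(forest, b) {
  f <- forest@forest
  stopifnot(b >= 1L, b <= length(f$bucket_idx))
  s <- f$bucket_start[b]; e <- f$bucket_end[b]
  build <- function(s, e) {
    if (s == e)
      return(list(kind = "member", pos = s, low = f$member_low[s],
                  height = 1L))
    mid <- (s + e) %/% 2L
    l <- build(s, mid); r <- build(mid + 1L, e)
    list(kind = "artificial", key = f$member_low[mid], left = l, right = r,
         height = 1L + max(l$height, r$height))
  }
  build(s, e)
}

#' @describeIn IndexedForest forest summary: forest node and bucket
#'   counts, nodes-per-bucket mean/sd, per-bucket BST heights with mean
#'   and max, source tree height, cut-off depth, and the number of
#'   attachments relocated from above the cut-off (`movedAttachments`
#'   counts source attachments once; `placedCopies` counts the copies
#'   placed on receiving members).
#' @export
setMethod("forestStats", "IndexedForest", function(x) {
  f <- x@forest
  sizes <- if (length(f$bucket_idx)) f$bucket_end - f$bucket_start + 1L
           else integer(0)
  list(nForestNodes = length(f$members),
       nBuckets = length(f$bucket_idx),
       nodesPerBucketMean = if (length(sizes)) mean(sizes) else 0,
       nodesPerBucketSd = if (length(sizes) > 1L) sd(sizes) else 0,
       bstHeights = f$bst_height,
       meanBstHeight = if (length(f$bst_height)) mean(f$bst_height) else 0,
       maxBstHeight = if (length(f$bst_height)) max(f$bst_height) else 0L,
       sourceHeight = x@tree@index$height,
       cutoffDepth = f$cutoff,
       movedAttachments = f$moved_attachments,
       placedCopies = f$placed_copies)
})

#' Structural validation of an indexed forest
#'
#' Asserts: member spans are strictly increasing, disjoint-consecutive and
#' partition the tree span; bucket hash indexes are strictly increasing
#' and agree with [hashIndex()] of each member's start; every member
#' belongs to exactly one bucket run; recorded BST heights equal the
#' heights of the explicit [bucketBST()] structures; and no interval is
#' lost by cutting (every stored interval remains reachable from some
#' member's short tree or relocation list).
#'
#' @param forest an [IndexedForest-class].
#' @return `TRUE` invisibly, or an error describing the violated property.
#' @export
validateForest <- function(forest) {
  f <- forest@forest
  idx <- forest@tree@index
  if (idx$root == 0L) return(invisible(TRUE))
  nm <- length(f$members)
  if (nm > 1L) {
    if (any(diff(f$member_low) <= 0L))
      stop("member starts not strictly increasing")
    if (any(f$member_low[-1L] != f$member_high[-nm] + 1L))
      stop("members not disjoint-consecutive")
  }
  if (f$member_low[1L] != idx$node_low[idx$root] ||
      f$member_high[nm] != idx$node_high[idx$root])
    stop("members do not cover the tree span")
  if (any(f$hidx != hashIndex(f$member_low, forest@preset)))
    stop("stored hash indexes disagree with hashIndex()")
  if (length(f$bucket_idx) > 1L && any(diff(f$bucket_idx) <= 0L))
    stop("bucket indexes not strictly increasing")
  cover <- integer(0)
  for (b in seq_along(f$bucket_idx)) {
    run <- f$bucket_start[b]:f$bucket_end[b]
    if (any(f$hidx[run] != f$bucket_idx[b]))
      stop("bucket run contains a foreign hash index")
    cover <- c(cover, run)
    bst <- bucketBST(forest, b)
    if (bst$height != f$bst_height[b])
      stop("recorded BST height disagrees with the explicit BST")
  }
  if (!identical(sort(cover), seq_len(nm)))
    stop("members not covered by exactly one bucket each")
  # no lost intervals: attachments at/below the cut-off or at childless
  # members stay in place; everything else must appear in a relocation list
  keep <- idx$depth >= f$cutoff
  keep[f$members] <- TRUE
  np <- diff(idx$canon_ptr)
  kept_ids <- idx$canon_idx[rep.int(keep, np)]
  reach <- sort(unique(c(kept_ids, f$reloc_idx)))
  if (!identical(reach, seq_len(idx$n_intervals)))
    stop("an interval was lost by cutting")
  invisible(TRUE)
}
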