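## n-way joint overlap by divide and conquer over the set list, per
## chromosome. Intermediate results are intersection REGIONS carrying one
## source uid per already-processed set, which makes the combine step
## associative; the engine (tree or forest) is always built on the smaller
## side of a combine and queried with the larger.

# internal record frame: list(low, high, contribs) with contribs a
# character matrix, one column per contributing input set (A-side columns
# always precede B-side columns)
.rec_frame <- function(low, high, contribs) {
  list(low = as.integer(low), high = as.integer(high), contribs = contribs)
}

.echo_frame <- function(d) {
  .rec_frame(d$low, d$high, matrix(d$uid, ncol = 1L))
}

.sort_frame <- function(fr) {
  if (!length(fr$low)) return(fr)
  keys <- c(list(fr$low, fr$high),
            lapply(seq_len(ncol(fr$contribs)), function(j) fr$contribs[, j]))
  ord <- do.call(order, keys)
  .rec_frame(fr$low[ord], fr$high[ord], fr$contribs[ord, , drop = FALSE])
}

.intersect_frames <- function(a, b, method = "st", percentage = 0.5,
                              preset = 1000000L) {
  ka <- ncol(a$contribs); kb <- ncol(b$contribs)
  if (!length(a$low) || !length(b$low))
    return(.rec_frame(integer(0), integer(0),
                      matrix(character(0), 0L, ka + kb)))
  build_on_a <- length(a$low) <= length(b$low)
  bd <- if (build_on_a) a else b
  qr <- if (build_on_a) b else a
  tree <- .st_build(bd$low, bd$high)
  if (method == "istf") {
    dummy <- new("SegmentTree", chrom = NA_character_,
                 intervals = data.frame(low = bd$low, high = bd$high,
                                        uid = rep("", length(bd$low))),
                 index = tree)
    cutoff <- decideCutoffDepth(dummy, percentage)
    forest <- .istf_build(tree, cutoff, as.integer(preset))
    hits <- .istf_query_intervals(tree, forest, qr$low, qr$high,
                                  as.integer(preset))
  } else {
    hits <- .st_query_intervals(tree, qr$low, qr$high)
  }
  qid <- hits$qid; iid <- hits$iid
  lowr <- pmax(bd$low[iid], qr$low[qid])
  highr <- pmin(bd$high[iid], qr$high[qid])
  contribs <- if (build_on_a)
    cbind(a$contribs[iid, , drop = FALSE], b$contribs[qid, , drop = FALSE])
  else
    cbind(a$contribs[qid, , drop = FALSE], b$contribs[iid, , drop = FALSE])
  .sort_frame(.rec_frame(lowr, highr, contribs))
}

# midpoint divide and conquer over the per-chromosome frame list
.joint_chrom <- function(frames, method, percentage, preset) {
  k <- length(frames)
  if (k == 1L) return(.sort_frame(frames[[1L]]))
  if (k == 2L)
    return(.intersect_frames(frames[[1L]], frames[[2L]], method,
                             percentage, preset))
  mid <- k %/% 2L
  .intersect_frames(
    .joint_chrom(frames[seq_len(mid)], method, percentage, preset),
    .joint_chrom(frames[(mid + 1L):k], method, percentage, preset),
    method, percentage, preset)
}

.frame_to_side <- function(x, what) {
  if (is(x, "IntervalSet")) {
    cn <- unique(x@data$chrom)
    if (length(cn) > 1L)
      stop(what, " spans several chromosomes; partition first")
    list(chrom = if (length(cn)) cn else NA_character_,
         frame = .echo_frame(x@data))
  } else if (is(x, "OverlapRecords")) {
    cn <- unique(x@chrom)
    if (length(cn) > 1L)
      stop(what, " spans several chromosomes; partition first")
    list(chrom = if (length(cn)) cn else NA_character_,
         frame = .rec_frame(x@low, x@high, x@contributors))
  } else stop(what, " must be an IntervalSet or OverlapRecords")
}

#' Intersect two interval collections on one chromosome
#'
#' The pairwise base case and combine step of the n-way recursion: builds
#' the search engine (segment tree, optionally converted to an indexed
#' forest) on the smaller collection and queries it with every element of
#' the larger. One record is emitted per overlapping pair, spanning
#' `[max(lows), min(highs)]`, with the contributor columns of `A`
#' preceding those of `B`. Output is sorted by (low, high, contributor
#' uids).
#'
#' @param A,B [IntervalSet-class] or [OverlapRecords-class] objects, each
#'   on a single, common chromosome (an error otherwise).
#' @param method `"st"` (segment tree) or `"istf"` (indexed forest); the
#'   two are equivalent by construction.
#' @param percentage,preset forest parameters, used when
#'   `method = "istf"`.
#' @return An [OverlapRecords-class].
#' @examples
#' A <- IntervalSet("chr1", 0L, 100L, setId = 1L)
#' B <- IntervalSet(c("chr1", "chr1"), c(10L, 30L), c(20L, 40L), setId = 2L)
#' as.data.frame(intersectTwo(A, B))
#' @export
intersectTwo <- function(A, B, method = c("st", "istf"), percentage = 0.5,
                         preset = 1000000L) {
  method <- match.arg(method)
  a <- .frame_to_side(A, "A"); b <- .frame_to_side(B, "B")
  chrom <- stats::na.omit(unique(c(a$chrom, b$chrom)))
  if (length(chrom) > 1L) stop("A and B are on different chromosomes")
  fr <- .intersect_frames(a$frame, b$frame, method, percentage, preset)
  OverlapRecords(rep(if (length(chrom)) chrom else NA_character_,
                     length(fr$low)),
                 fr$low, fr$high, fr$contribs)
}

#' Joint overlap of n interval sets
#'
#' Finds all regions covered by at least one interval from every input
#' set, reported per contributing tuple. The set list is split
#' recursively at its midpoint; a single set is echoed as unit records, a
#' pair and every combine step go through [intersectTwo()]. Chromosomes
#' are processed independently (only chromosomes present in every set can
#' contribute) and results are concatenated in sorted chromosome order,
#' so the output is identical for any `workers` value.
#'
#' @param sets list of [IntervalSet-class] objects (at least one).
#' @param method `"st"` or `"istf"`.
#' @param workers number of worker processes for per-chromosome
#'   parallelism (forked; values > 1 require a Unix-alike).
#' @param percentage,preset forest parameters for `method = "istf"`.
#' @return An [OverlapRecords-class] with one contributor column per set.
#' @examples
#' sets <- list(IntervalSet("chr1", 1L, 10L, setId = 1L),
#'              IntervalSet("chr1", 5L, 15L, setId = 2L),
#'              IntervalSet("chr1", 8L, 20L, setId = 3L))
#' as.data.frame(jointOverlap(sets))  # one record: chr1 [8, 10]
#' @export
jointOverlap <- function(sets, method = c("st", "istf"), workers = 1L,
                         percentage = 0.5, preset = 1000000L) {
  method <- match.arg(method)
  if (!length(sets)) stop("at least one interval set required")
  if (!all(vapply(sets, is, logical(1), "IntervalSet")))
    stop("all elements of `sets` must be IntervalSet objects")
  stopifnot(workers >= 1L)
  parts <- lapply(sets, chromPartition)
  chroms <- Reduce(intersect, lapply(parts, names))
  chroms <- sort(chroms)
  one_chrom <- function(ch) {
    frames <- lapply(parts, function(p) .echo_frame(p[[ch]]))
    .joint_chrom(frames, method, percentage, preset)
  }
  res <- if (workers > 1L && length(chroms) > 1L)
    parallel::mclapply(chroms, one_chrom, mc.cores = workers)
  else lapply(chroms, one_chrom)
  k <- length(sets)
  chrom <- rep(chroms, vapply(res, function(r) length(r$low), integer(1)))
  OverlapRecords(chrom,
                 unlist(lapply(res, `[[`, "low"), use.names = FALSE),
                 unlist(lapply(res, `[[`, "high"), use.names = FALSE),
                 do.call(rbind, c(lapply(res, `[[`, "contribs"),
                                  list(matrix(character(0), 0L, k)))))
}
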