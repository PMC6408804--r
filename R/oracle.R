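## Brute-force reference used throughout testing. Deliberately shares no
## code with the segment-tree / forest engines: the all-pairs variant is a
## vectorised cross product, the sweep variant a two-pointer scan over
## start-sorted copies. Both reproduce the same record semantics (one
## record per overlapping pair, intersection region, A-side contributor
## columns first, sorted by (low, high, contributor uids)).

# all overlapping (i, j) pairs, i indexing a, j indexing b
.oracle_pairs_allpairs <- function(alow, ahigh, blow, bhigh) {
  if (!length(alow) || !length(blow))
    return(list(i = integer(0), j = integer(0)))
  m <- outer(alow, bhigh, "<=") & t(outer(blow, ahigh, "<="))
  w <- which(m, arr.ind = TRUE)
  list(i = as.integer(w[, 1L]), j = as.integer(w[, 2L]))
}

.oracle_pairs_sweep <- function(alow, ahigh, blow, bhigh) {
  na <- length(alow); nb <- length(blow)
  if (!na || !nb) return(list(i = integer(0), j = integer(0)))
  # merged start-order sweep: when an interval opens, it pairs with every
  # still-alive interval of the other set that reaches its start
  ev_low <- c(alow, blow)
  ev_set <- rep(1:2, c(na, nb))
  ev_id <- c(seq_len(na), seq_len(nb))
  ii <- integer(0); jj <- integer(0)
  activeA <- activeB <- integer(0)
  for (t in order(ev_low, ev_set)) {
    id <- ev_id[t]
    if (ev_set[t] == 1L) {
      activeB <- activeB[bhigh[activeB] >= alow[id]]
      ii <- c(ii, rep(id, length(activeB))); jj <- c(jj, activeB)
      activeA <- c(activeA, id)
    } else {
      activeA <- activeA[ahigh[activeA] >= blow[id]]
      ii <- c(ii, activeA); jj <- c(jj, rep(id, length(activeA)))
      activeB <- c(activeB, id)
    }
  }
  list(i = ii, j = jj)
}

.oracle_records <- function(a, b, pairs) {
  low <- pmax(a$low[pairs$i], b$low[pairs$j])
  high <- pmin(a$high[pairs$i], b$high[pairs$j])
  contribs <- cbind(a$contribs[pairs$i, , drop = FALSE],
                    b$contribs[pairs$j, , drop = FALSE])
  if (length(low)) {
    keys <- c(list(low, high),
              lapply(seq_len(ncol(contribs)), function(j) contribs[, j]))
    ord <- do.call(order, keys)
    low <- low[ord]; high <- high[ord]
    contribs <- contribs[ord, , drop = FALSE]
  }
  list(low = as.integer(low), high = as.integer(high), contribs = contribs)
}

.oracle_side <- function(x, what) {
  if (is(x, "IntervalSet")) {
    cn <- unique(x@data$chrom)
    if (length(cn) > 1L) stop(what, " spans several chromosomes")
    list(chrom = if (length(cn)) cn else NA_character_,
         low = x@data$low, high = x@data$high,
         contribs = matrix(x@data$uid, ncol = 1L))
  } else if (is(x, "OverlapRecords")) {
    cn <- unique(x@chrom)
    if (length(cn) > 1L) stop(what, " spans several chromosomes")
    list(chrom = if (length(cn)) cn else NA_character_,
         low = x@low, high = x@high, contribs = x@contributors)
  } else stop(what, " must be an IntervalSet or OverlapRecords")
}

#' Brute-force pairwise intersection (reference oracle)
#'
#' Independent re-implementation of [intersectTwo()]'s record semantics
#' with no tree or forest involved: `"allpairs"` tests every (a, b) pair
#' with a vectorised cross product; `"sweep"` scans start-sorted copies
#' with two pointers. Intended for desk-scale verification inputs.
#'
#' @param A,B [IntervalSet-class] or [OverlapRecords-class] on one common
#'   chromosome.
#' @param variant `"allpairs"` (default) or `"sweep"`.
#' @return An [OverlapRecords-class].
#' @export
oracleIntersectTwo <- function(A, B, variant = c("allpairs", "sweep")) {
  variant <- match.arg(variant)
  a <- .oracle_side(A, "A"); b <- .oracle_side(B, "B")
  chrom <- stats::na.omit(unique(c(a$chrom, b$chrom)))
  if (length(chrom) > 1L) stop("A and B are on different chromosomes")
  pairs <- if (variant == "sweep")
    .oracle_pairs_sweep(a$low, a$high, b$low, b$high)
  else .oracle_pairs_allpairs(a$low, a$high, b$low, b$high)
  r <- .oracle_records(a, b, pairs)
  OverlapRecords(rep(if (length(chrom)) chrom else NA_character_,
                     length(r$low)),
                 r$low, r$high, r$contribs)
}

#' Brute-force n-way joint overlap (reference oracle)
#'
#' Left-to-right fold of [oracleIntersectTwo()] over the set list, per
#' chromosome present in every set, concatenated in sorted chromosome
#' order. Because intersection of regions is associative, this must equal
#' [jointOverlap()] for any split order, which is what the test-suite
#' equivalence checks assert.
#'
#' @param sets list of [IntervalSet-class] objects.
#' @param variant passed to [oracleIntersectTwo()].
#' @return An [OverlapRecords-class].
#' @export
oracleJoint <- function(sets, variant = c("allpairs", "sweep")) {
  variant <- match.arg(variant)
  if (!length(sets)) stop("at least one interval set required")
  parts <- lapply(sets, function(s)
    split(s@data, factor(s@data$chrom, levels = unique(s@data$chrom))))
  chroms <- sort(Reduce(intersect, lapply(parts, names)))
  k <- length(sets)
  chrom_out <- character(0); low_out <- integer(0); high_out <- integer(0)
  contrib_out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    d1 <- parts[[1L]][[ch]]
    acc <- list(low = d1$low, high = d1$high,
                contribs = matrix(d1$uid, ncol = 1L))
    if (k == 1L && length(acc$low)) {  # echo, sorted like the engines
      keys <- list(acc$low, acc$high, acc$contribs[, 1L])
      ord <- do.call(order, keys)
      acc <- list(low = acc$low[ord], high = acc$high[ord],
                  contribs = acc$contribs[ord, , drop = FALSE])
    }
    if (k > 1L) for (s in 2:k) {
      d <- parts[[s]][[ch]]
      nxt <- list(low = d$low, high = d$high,
                  contribs = matrix(d$uid, ncol = 1L))
      pairs <- if (variant == "sweep")
        .oracle_pairs_sweep(acc$low, acc$high, nxt$low, nxt$high)
      else .oracle_pairs_allpairs(acc$low, acc$high, nxt$low, nxt$high)
      acc <- .oracle_records(acc, nxt, pairs)
    }
    chrom_out <- c(chrom_out, rep(ch, length(acc$low)))
    low_out <- c(low_out, acc$low)
    high_out <- c(high_out, acc$high)
    contrib_out[[ci]] <- acc$contribs
  }
  OverlapRecords(chrom_out, low_out, high_out,
                 do.call(rbind, c(contrib_out,
                                  list(matrix(character(0), 0L, k)))))
}
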