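## Semi-synthetic dataset generation: fixed-length intervals with start
## positions sampled uniformly over human-scale chromosomes, plus
## adversarial fixtures exercising nesting, duplication, shared endpoints,
## adjacency, point intervals and unsorted order.

# run expr with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Human-scale reference genome model
#'
#' The 24 nuclear chromosomes with hg19-scale lengths, used as the default
#' sampling space for the uniform generator. Override with
#' [readChromSizes()] for any other assembly.
#'
#' @return A [GenomeModel-class].
#' @export
hg19Genome <- function() {
  GenomeModel(c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
    chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
    chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
    chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
    chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
    chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
    chr22 = 51304566, chrX = 155270560, chrY = 59373566))
}

#' Generate uniformly sampled fixed-length interval sets
#'
#' For every interval: a chromosome is drawn with probability proportional
#' to its length (restricted to chromosomes at least `intervalLen` long),
#' the start uniformly from `[0, length - intervalLen]`, and the interval
#' spans `intervalLen` bases. One RNG stream seeded once drives all
#' files, so a given `(seed, nFiles, nIntervals, intervalLen, genome)`
#' reproduces byte-identical output.
#'
#' @param nFiles number of interval sets to generate (>= 1).
#' @param nIntervals intervals per set.
#' @param intervalLen fixed interval length in bp (default 500).
#' @param genome a [GenomeModel-class]; default [hg19Genome()].
#' @param seed mandatory integer seed.
#' @param dir if non-NULL, additionally write each set as
#'   `uniform_<i>.bed` under `dir` and attach the paths as attribute
#'   `paths`.
#' @return list of [IntervalSet-class] objects (setIds 1..nFiles).
#' @export
generateUniformSets <- function(nFiles, nIntervals, intervalLen = 500L,
                                genome = hg19Genome(), seed, dir = NULL) {
  stopifnot(nFiles >= 1L, nIntervals >= 0L, intervalLen >= 1L)
  if (missing(seed)) stop("a seed is required")
  sizes <- chromLengths(genome)
  if (intervalLen > max(sizes))
    stop("intervalLen exceeds the longest chromosome")
  sizes <- sizes[sizes >= intervalLen]
  .with_seed(seed, {
    sets <- lapply(seq_len(nFiles), function(i) {
      ci <- sample.int(length(sizes), nIntervals, replace = TRUE,
                       prob = sizes)
      start <- floor(runif(nIntervals) * (sizes[ci] - intervalLen + 1))
      IntervalSet(names(sizes)[ci], as.integer(start),
                  as.integer(start) + as.integer(intervalLen) - 1L,
                  setId = i)
    })
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- vapply(seq_along(sets), function(i) {
        p <- file.path(dir, sprintf("uniform_%d.bed", i))
        d <- sets[[i]]@data
        write.table(data.frame(d$chrom, d$low, d$high + 1L), p,
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        p
      }, character(1))
      attr(sets, "paths") <- paths
    }
    sets
  })
}

#' Generate an adversarial interval set
#'
#' A deterministic torture fixture on two chromosomes mixing a nested
#' chain, exact duplicates, shared low and high endpoints, an
#' adjacent-but-disjoint pair, and point intervals, padded with random
#' intervals up to `max(size, 13)` records and shuffled so the output is
#' never sorted by start.
#'
#' @param seed integer seed; the same seed reproduces the same set.
#' @param size requested number of intervals (>= 1; at least 13 are
#'   produced so that every pattern is present).
#' @param setId set index for the produced [IntervalSet-class].
#' @return An [IntervalSet-class].
#' @export
generateAdversarial <- function(seed, size = 50L, setId = 1L) {
  stopifnot(size >= 1L)
  n <- max(as.integer(size), 13L)
  .with_seed(seed, {
    span <- 5000L
    base <- as.integer(sample.int(span, 1L)) + 100L
    core <- data.frame(
      chrom = c(rep("chrA", 10L), "chrB", "chrB"),
      low = c(base, base + 50L, base + 100L,    # nested chain
              base, base,                       # exact duplicates
              base + 600L, base + 600L,         # shared low endpoint
              base + 900L, base + 950L,         # shared high endpoint
              base + 1200L,                     # adjacent pair, left
              10L, 10L),                        # chrB: point + duplicate
      high = c(base + 400L, base + 300L, base + 200L,
               base + 20L, base + 20L,
               base + 700L, base + 650L,
               base + 1000L, base + 1000L,
               base + 1209L,
               10L, 10L),
      stringsAsFactors = FALSE)
    core <- rbind(core, data.frame(chrom = "chrA", low = base + 1210L,
                                   high = base + 1219L))  # adjacent, right
    extra <- n - nrow(core)
    if (extra > 0L) {
      lo <- as.integer(sample.int(span, extra, replace = TRUE))
      len <- as.integer(sample.int(400L, extra, replace = TRUE))
      core <- rbind(core, data.frame(
        chrom = sample(c("chrA", "chrB"), extra, replace = TRUE),
        low = lo, high = lo + len - 1L, stringsAsFactors = FALSE))
    }
    ord <- sample.int(nrow(core))
    core <- core[ord, , drop = FALSE]
    if (!is.unsorted(core$low)) core <- core[rev(seq_len(nrow(core))), ]
    IntervalSet(core$chrom, core$low, core$high, setId = setId)
  })
}
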