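## BED3+ input/output. BED is 0-based half-open; internally an interval is
## the inclusive integer range [start, end - 1]. Records with end <= start
## denote empty intervals and are dropped with a count, not an error.

#' Read a BED file into an IntervalSet
#'
#' Reads BED3+ records (tab- or space-delimited). `track`, `browser` and
#' `#` comment lines and blank lines are skipped; extra columns beyond the
#' third are ignored. Each record `[start, end)` becomes the inclusive
#' interval `[start, end - 1]`; records with `end <= start` are dropped and
#' counted (see [droppedRecords()]). Input order is preserved.
#'
#' @param path BED file path.
#' @param setId integer index of this input set within the run; uids are
#'   assigned as `"s<setId>.<i>"` with `i` the record number among kept
#'   records.
#' @return An [IntervalSet-class]; empty files give an empty set.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t5\t8", "chr2\t0\t4"), bed)
#' readBed(bed)
#' @export
readBed <- function(path, setId = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(IntervalSet(character(0), integer(0), integer(0),
                       setId = setId))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("line %d: fewer than 3 fields", lineno[which(nf < 3L)[1]]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad))
    stop(sprintf("line %d: non-integer coordinate", lineno[which(bad)[1]]))
  empty <- e <= s
  IntervalSet(chrom[!empty], as.integer(s[!empty]),
              as.integer(e[!empty]) - 1L, setId = setId,
              dropped = sum(empty))
}

#' Write overlap records as BED
#'
#' Back-converts inclusive regions to BED half-open coordinates
#' (`start = low`, `end = high + 1`) and writes them sorted by
#' (chrom, start, end) for determinism. With `emitSources`, one extra
#' column per contributing input set lists that set's source uid.
#'
#' @param records an [OverlapRecords-class] object.
#' @param path output file path.
#' @param emitSources emit provenance columns (one uid column per set).
#' @return Invisibly, the number of lines written.
#' @export
writeOverlaps <- function(records, path, emitSources = FALSE) {
  stopifnot(is(records, "OverlapRecords"))
  n <- length(records@low)
  if (n == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write: ", path)
    return(invisible(0L))
  }
  d <- data.frame(chrom = records@chrom, start = records@low,
                  end = records@high + 1L, stringsAsFactors = FALSE)
  keycols <- list(d$chrom, d$start, d$end)
  if (emitSources && ncol(records@contributors) > 0) {
    for (j in seq_len(ncol(records@contributors)))
      d[[sprintf("uid%d", j)]] <- records@contributors[, j]
    keycols <- c(keycols,
                 lapply(seq_len(ncol(records@contributors)),
                        function(j) records@contributors[, j]))
  }
  d <- d[do.call(order, keycols), , drop = FALSE]
  ok <- tryCatch({
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(n)
}

#' Read overlap regions back from a BED file
#'
#' Inverse of [writeOverlaps()] for the coordinate columns; provenance
#' columns, when present, are restored into the contributors matrix.
#'
#' @param path BED file written by [writeOverlaps()].
#' @return An [OverlapRecords-class].
#' @export
readOverlaps <- function(path) {
  iv <- readBed(path)
  d <- iv@data
  extra <- {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) &
                     nzchar(trimws(lines))]
    if (length(lines)) strsplit(trimws(lines), "[ \t]+") else list()
  }
  k <- if (length(extra)) max(0L, min(lengths(extra)) - 3L) else 0L
  contrib <- if (k > 0 && nrow(d) > 0) {
    do.call(cbind, lapply(seq_len(k) + 3L, function(j)
      vapply(extra, `[[`, character(1), j)))
  } else matrix(character(0), nrow = nrow(d), ncol = max(k, 0L))
  OverlapRecords(d$chrom, d$low, d$high, contrib)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#'
#' @param path chrom.sizes file path.
#' @return A [GenomeModel-class].
#' @export
readChromSizes <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("chrom.sizes needs two columns (name, length)")
  sizes <- as.numeric(d[[2L]])
  names(sizes) <- as.character(d[[1L]])
  GenomeModel(sizes)
}
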