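# Shared fixture builders. All randomness is locally seeded so every test
# is reproducible in isolation.

# canonical multiset key of an OverlapRecords object: one string per
# record carrying chrom, coordinates and the full contributor tuple
rec_key <- function(r) {
  d <- as.data.frame(r)
  if (!nrow(d)) return(character(0))
  sort(do.call(paste, c(d, sep = "|")))
}

# a list of small random interval sets on a two-chromosome toy genome;
# sizes and density chosen so n-way tuple counts stay at desk scale
random_sets <- function(seed, n_sets = NULL, n_range = c(5L, 80L),
                        span = 3000L, max_len = 300L,
                        chroms = c("c1", "c2")) {
  set.seed(seed)
  if (is.null(n_sets)) n_sets <- sample(2:6, 1)
  lapply(seq_len(n_sets), function(i) {
    n <- sample(seq(n_range[1], n_range[2]), 1)
    lo <- sample.int(span, n, replace = TRUE)
    len <- sample.int(max_len, n, replace = TRUE)
    IntervalSet(sample(chroms, n, replace = TRUE), lo, lo + len - 1L,
                setId = i)
  })
}

# a mixed fixture used by the acceptance checks: 2..16 sets, occasionally
# large (up to 2000 intervals per set), adversarial sets blended in on
# every third seed
acceptance_fixture <- function(seed) {
  set.seed(seed)
  if (seed %% 3 == 0) {
    # all-adversarial fixture: nested chains, duplicates, shared
    # endpoints, adjacency, point intervals, unsorted order
    n_sets <- sample(2:4, 1)
    sets <- lapply(seq_len(n_sets), function(i)
      generateAdversarial(seed * 31L + i, size = sample(30:80, 1),
                          setId = i))
  } else if (seed %% 10 == 0) {
    # two large dense sets
    sets <- lapply(1:2, function(i) {
      n <- 2000L
      lo <- sample.int(600000L, n, replace = TRUE)
      len <- sample.int(600L, n, replace = TRUE)
      IntervalSet(sample(c("c1", "c2"), n, replace = TRUE), lo,
                  lo + len - 1L, setId = i)
    })
  } else {
    n_sets <- sample(2:16, 1)
    sets <- lapply(seq_len(n_sets), function(i) {
      n <- sample(20:300, 1)
      lo <- sample.int(1000000L, n, replace = TRUE)
      len <- sample.int(1000L, n, replace = TRUE)
      IntervalSet(sample(c("c1", "c2"), n, replace = TRUE), lo,
                  lo + len - 1L, setId = i)
    })
  }
  sets
}

# single-chromosome interval table for direct engine-level checks
random_chrom_df <- function(seed, n = 60L, span = 3000L, max_len = 300L) {
  set.seed(seed)
  lo <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(low = lo, high = lo + len - 1L,
             uid = sprintf("u%d", seq_len(n)), stringsAsFactors = FALSE)
}
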