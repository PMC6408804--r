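test_that("elementary partition follows the endpoint rule", {
  p <- elementaryPartition(c(2L, 5L), c(5L, 9L))
  expect_equal(p$endpoints, c(2L, 5L, 9L))
  expect_equal(p$leaves$low, c(2L, 3L, 5L, 6L, 9L))
  expect_equal(p$leaves$high, c(2L, 4L, 5L, 8L, 9L))

  p1 <- elementaryPartition(4L, 4L)          # point interval
  expect_equal(p1$endpoints, 4L)
  expect_equal(unlist(p1$leaves), c(low = 4L, high = 4L))

  p2 <- elementaryPartition(c(0L, 1L), c(1L, 2L))  # adjacent endpoints
  expect_equal(p2$leaves$low, 0:2)
  expect_equal(p2$leaves$high, 0:2)

  expect_error(elementaryPartition(integer(0), integer(0)), "empty")
})

test_that("leaves partition the span: disjoint, consecutive, covering", {
  for (seed in 1:25) {
    d <- random_chrom_df(seed, n = 40L)
    p <- elementaryPartition(d$low, d$high)
    expect_true(all(diff(p$leaves$low) > 0))
    expect_equal(p$leaves$low[-1L],
                 p$leaves$high[-nrow(p$leaves)] + 1L)
    expect_equal(p$leaves$low[1L], min(p$endpoints))
    expect_equal(p$leaves$high[nrow(p$leaves)], max(p$endpoints))
    expect_true(all(p$endpoints %in% p$leaves$low[p$leaves$low ==
                                                    p$leaves$high]))
  }
})

test_that("canonical subsets satisfy the containment rules", {
  # one interval spanning the whole partition lands at the root only
  d <- data.frame(low = c(2L, 5L), high = c(9L, 9L), uid = c("a", "b"))
  tr <- buildSegmentTree(d, chrom = "c")
  idx <- tr@index
  root_can <- idx$canon_idx[idx$canon_ptr[idx$root]:
                              (idx$canon_ptr[idx$root + 1L] - 1L)]
  expect_equal(root_can, 1L)  # [2,9] covers Int(root) = [2,9]
  expect_true(validateSegmentTree(tr))

  d1 <- data.frame(low = 3L, high = 7L, uid = "x")
  tr1 <- buildSegmentTree(d1, chrom = "c")
  expect_equal(nStored(tr1), 1L)
  expect_equal(treeStats(tr1)$attachmentsByDepth[["0"]], 1L)

  for (seed in 1:30) {
    tr <- buildSegmentTree(random_chrom_df(seed), chrom = "c")
    expect_true(validateSegmentTree(tr))  # includes <= 2 per depth level
  }
})

test_that("tree shape: bottom-up balanced, height bounded", {
  for (seed in 1:20) {
    tr <- buildSegmentTree(random_chrom_df(seed, n = 50L), chrom = "c")
    expect_lte(treeHeight(tr), ceiling(log2(nLeaves(tr))) + 1L)
    # leaves of the flat tree are exactly the elementary partition
    d <- tr@intervals
    p <- elementaryPartition(d$low, d$high)
    leaf <- which(tr@index$left == 0L)
    leaf <- leaf[order(tr@index$node_low[leaf])]
    expect_equal(tr@index$node_low[leaf], p$leaves$low)
    expect_equal(tr@index$node_high[leaf], p$leaves$high)
  }
})

test_that("point queries match a linear scan and visit few nodes", {
  d <- data.frame(low = c(1L, 3L), high = c(5L, 8L), uid = c("a", "b"))
  tr <- buildSegmentTree(d, chrom = "c")
  expect_setequal(queryPoint(tr, 4L)$uid, c("a", "b"))
  expect_equal(nrow(queryPoint(tr, 0L)), 0L)     # left of all endpoints
  expect_equal(queryPoint(tr, 8L)$uid, "b")       # inclusive endpoint

  for (seed in 1:20) {
    d <- random_chrom_df(seed)
    tr <- buildSegmentTree(d, chrom = "c")
    for (x in sample.int(3500L, 25L)) {
      res <- queryPoint(tr, x)
      expect_identical(sort(res$uid), sort(d$uid[d$low <= x & d$high >= x]))
      expect_lte(attr(res, "nodesVisited"), treeHeight(tr) + 1L)
    }
  }
})

test_that("interval queries match the all-pairs overlap test", {
  d <- data.frame(low = c(1L, 3L, 20L), high = c(5L, 8L, 30L),
                  uid = c("a", "b", "c"))
  tr <- buildSegmentTree(d, chrom = "c")
  expect_equal(queryInterval(tr, 6L, 10L)$uid, "b")
  expect_equal(nrow(queryInterval(tr, 9L, 19L)), 0L)

  # nested case: query inside both a container and its contained interval
  d2 <- data.frame(low = c(0L, 10L), high = c(100L, 20L), uid = c("a", "b"))
  tr2 <- buildSegmentTree(d2, chrom = "c")
  expect_setequal(queryInterval(tr2, 15L, 15L)$uid, c("a", "b"))

  # a single shared base counts as overlap
  tr3 <- buildSegmentTree(data.frame(low = 1L, high = 5L, uid = "a"),
                          chrom = "c")
  expect_equal(queryInterval(tr3, 5L, 9L)$uid, "a")

  for (seed in 1:20) {
    d <- random_chrom_df(seed)
    tr <- buildSegmentTree(d, chrom = "c")
    set.seed(seed + 1000L)
    for (k in 1:25) {
      ql <- sample.int(3500L, 1); qh <- ql + sample.int(400L, 1)
      got <- sort(queryInterval(tr, ql, qh)$uid)
      want <- sort(d$uid[d$low <= qh & ql <= d$high])
      expect_identical(got, want)
    }
  }
})

test_that("duplicates are stored and reported per record", {
  d <- data.frame(low = rep(3L, 4L), high = rep(7L, 4L),
                  uid = sprintf("d%d", 1:4))
  tr <- buildSegmentTree(d, chrom = "c")
  expect_equal(nStored(tr), 4L)
  expect_setequal(queryPoint(tr, 5L)$uid, d$uid)
})

test_that("tree statistics conserve attachments; empty tree is all-zero", {
  for (seed in 1:10) {
    tr <- buildSegmentTree(random_chrom_df(seed), chrom = "c")
    st <- treeStats(tr)
    expect_equal(sum(st$attachmentsByDepth), st$nStored)
  }
  empty <- buildSegmentTree(data.frame(low = integer(0), high = integer(0),
                                       uid = character(0)), chrom = "c")
  st <- treeStats(empty)
  expect_equal(st$height, 0L)
  expect_equal(st$nLeaves, 0L)
  expect_equal(st$nStored, 0L)
  expect_equal(nrow(queryInterval(empty, 1L, 10L)), 0L)
})

test_that("storage bound: attachments per interval within 2 x height", {
  for (seed in 1:10) {
    tr <- buildSegmentTree(random_chrom_df(seed, n = 80L), chrom = "c")
    per <- tabulate(tr@index$canon_idx, nbins = nrow(tr@intervals))
    expect_lte(max(per), 2L * max(treeHeight(tr), 1L))
    expect_lte(nStored(tr),
               2L * max(treeHeight(tr), 1L) * nrow(tr@intervals))
  }
})
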