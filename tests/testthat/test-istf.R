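test_that("cut-off depth follows the cumulative-percentage rule", {
  # independent recomputation from the attachments-by-depth profile
  for (seed in 1:15) {
    tr <- buildSegmentTree(random_chrom_df(seed), chrom = "c")
    st <- treeStats(tr)
    for (pct in c(0.5, 1, 5, 25, 60)) {
      cum <- cumsum(st$attachmentsByDepth)
      d <- which(cum > pct / 100 * st$nStored)[1L] - 1L
      want <- if (is.na(d)) st$height else min(d + 1L, st$height)
      expect_equal(decideCutoffDepth(tr, pct), want)
    }
  }
  # percentage 100 can never be exceeded: clamps to the height
  tr <- buildSegmentTree(random_chrom_df(1), chrom = "c")
  expect_equal(decideCutoffDepth(tr, 100), treeHeight(tr))
  # degenerate single-leaf tree clamps to height 0
  tr0 <- buildSegmentTree(data.frame(low = 5L, high = 5L, uid = "p"),
                          chrom = "c")
  expect_equal(decideCutoffDepth(tr0, 0.5), 0L)
  empty <- buildSegmentTree(data.frame(low = integer(0),
                                       high = integer(0),
                                       uid = character(0)), chrom = "c")
  expect_error(decideCutoffDepth(empty, 0.5), "empty")
  expect_error(decideCutoffDepth(tr, 0), "percentage")
})

test_that("cut-off depth: sparse-top profile picks d + 1", {
  # 6 attachments reachable at depths 0..3, the rest at deeper nodes:
  # with percentage 0.5 and 1000 attachments the threshold is 5, the
  # smallest depth with cumulative > 5 is 3, so the cut-off is 4
  tr <- buildSegmentTree(random_chrom_df(42, n = 600L, span = 20000L),
                         chrom = "c")
  st <- treeStats(tr)
  cum <- cumsum(st$attachmentsByDepth)
  thr <- 0.5 / 100 * st$nStored
  d <- which(cum > thr)[1L] - 1L
  expect_equal(decideCutoffDepth(tr, 0.5), min(d + 1L, st$height))
  expect_gt(cum[[d + 1L]], thr)
  if (d > 0L) expect_lte(cum[[d]], thr)
})

test_that("hash index is floor division of the start coordinate", {
  expect_equal(hashIndex(2345678L, 1000000L), 2L)
  expect_equal(hashIndex(0L, 17L), 0L)
  expect_equal(hashIndex(999999L, 1000000L), 0L)
  expect_equal(hashIndex(c(0L, 5L, 10L), 5L), c(0L, 1L, 2L))
  expect_error(hashIndex(5L, 0L), "positive")
  expect_error(hashIndex(-1L, 5L), "non-negative")
})

test_that("forest build relocates every attachment above the cut-off", {
  for (seed in 1:20) {
    tr <- buildSegmentTree(random_chrom_df(seed), chrom = "c")
    for (pct in c(0.5, 10, 80)) for (preset in c(50L, 1000L, 10000000L)) {
      fr <- buildForest(tr, percentage = pct, preset = preset)
      expect_true(validateForest(fr))
    }
  }
})

test_that("a root-spanning interval survives the cut and stays queryable", {
  set.seed(7)
  d <- random_chrom_df(7, n = 40L)
  whole <- data.frame(low = min(d$low), high = max(d$high), uid = "span")
  d <- rbind(whole, d)
  tr <- buildSegmentTree(d, chrom = "c")
  fr <- buildForest(tr, percentage = 0.5, preset = 100L)
  expect_gte(fr@forest$moved_attachments, 1L)
  for (k in 1:30) {
    ql <- sample.int(3500L, 1); qh <- ql + sample.int(300L, 1)
    expect_identical(sort(queryInterval(fr, ql, qh)$uid),
                     sort(queryInterval(tr, ql, qh)$uid))
  }
  # the spanning interval is found wherever its span is probed
  expect_true("span" %in% queryInterval(fr, whole$low, whole$low)$uid)
  expect_true("span" %in% queryInterval(fr, whole$high, whole$high)$uid)
})

test_that("no attachments above the cut-off means nothing moves", {
  # point intervals attach only at their (childless) point leaves, which
  # are forest members themselves: cutting relocates nothing
  d <- data.frame(low = c(10L, 20L, 30L), high = c(10L, 20L, 30L),
                  uid = c("a", "b", "c"))
  tr <- buildSegmentTree(d, chrom = "c")
  fr <- buildForest(tr, percentage = 99.9, preset = 1000000L)
  expect_equal(fr@forest$moved_attachments, 0L)
  for (q in list(c(10L, 10L), c(1L, 40L), c(13L, 19L)))
    expect_identical(sort(queryInterval(fr, q[1], q[2])$uid),
                     sort(queryInterval(tr, q[1], q[2])$uid))
})

test_that("preset beyond the chromosome span gives a single bucket", {
  tr <- buildSegmentTree(random_chrom_df(3), chrom = "c")
  fr <- buildForest(tr, preset = 100000000L)
  expect_equal(bucketCount(fr), 1L)
  expect_equal(fr@forest$bucket_idx, 0L)
  expect_equal(fr@forest$bucket_end[1L] - fr@forest$bucket_start[1L] + 1L,
               nForestNodes(fr))
})

test_that("start-node cascade resolves through the documented branches", {
  # members spread over hash indexes ~ [1..35] with preset 100
  d <- data.frame(low = c(100L, 150L, 220L, 3500L),
                  high = c(400L, 300L, 260L, 3600L),
                  uid = sprintf("u%d", 1:4))
  tr <- buildSegmentTree(d, chrom = "c")
  fr <- buildForest(tr, percentage = 50, preset = 100L)
  occupied <- fr@forest$bucket_idx
  # query landing in an occupied bucket
  s1 <- lookupStart(fr, 150L, 160L)
  expect_equal(s1$branch, "lowIndex")
  expect_true(s1$interval[1] <= 150L)
  # query in an interior coordinate gap: resolved leftward
  gap_idx <- setdiff(seq(min(occupied), max(occupied)), occupied)
  expect_true(length(gap_idx) > 0)
  s2 <- lookupStart(fr, gap_idx[1] * 100L, gap_idx[1] * 100L + 50L)
  expect_equal(s2$branch, "lowerIndex")
  # query fully left of the first forest node: highIndex/higherIndex path
  s3 <- lookupStart(fr, 0L, 99L)
  expect_true(s3$branch %in% c("highIndex", "higherIndex"))
  # query right of all nodes: the lowerIndex start yields no overlap
  s4 <- lookupStart(fr, 10000L, 10100L)
  expect_equal(s4$branch, "lowerIndex")
  expect_equal(nrow(queryInterval(fr, 10000L, 10100L)), 0L)
  # wide query spanning past both ends still finds everything
  expect_setequal(queryInterval(fr, 0L, 100000L)$uid, d$uid)
})

test_that("forest queries equal tree queries on every fixture", {
  for (seed in 1:25) {
    d <- random_chrom_df(seed)
    tr <- buildSegmentTree(d, chrom = "c")
    set.seed(seed + 500L)
    pct <- sample(c(0.5, 2, 20), 1)
    preset <- sample(c(64L, 512L, 5000L), 1)
    fr <- buildForest(tr, percentage = pct, preset = preset)
    for (k in 1:30) {
      ql <- sample.int(4000L, 1); qh <- ql + sample.int(500L, 1)
      res <- queryInterval(fr, ql, qh)
      expect_identical(sort(res$uid), sort(queryInterval(tr, ql, qh)$uid))
      expect_lte(attr(res, "extraNodes"), 2L)
    }
  }
})

test_that("collision BSTs are balanced with artificial routing nodes", {
  tr <- buildSegmentTree(random_chrom_df(11, n = 100L), chrom = "c")
  fr <- buildForest(tr, percentage = 30, preset = 200L)
  f <- fr@forest
  for (b in seq_along(f$bucket_idx)) {
    bst <- bucketBST(fr, b)
    expect_equal(bst$height, f$bst_height[b])
    k <- f$bucket_end[b] - f$bucket_start[b] + 1L
    if (k == 1L) {
      expect_equal(bst$kind, "member")
      expect_equal(bst$height, 1L)
    } else {
      expect_equal(bst$kind, "artificial")
      # in-order traversal of members is sorted by start coordinate
      inorder <- function(n) {
        if (n$kind == "member") n$low
        else c(inorder(n$left), inorder(n$right))
      }
      expect_equal(inorder(bst),
                   f$member_low[f$bucket_start[b]:f$bucket_end[b]])
    }
  }
})

test_that("forest statistics summarise buckets and relocations", {
  # all-singleton buckets (preset 1: one bucket per start): mean 1,
  # every BST height 1
  d <- data.frame(low = c(0L, 1000L, 2000L), high = c(10L, 1010L, 2010L),
                  uid = c("a", "b", "c"))
  tr <- buildSegmentTree(d, chrom = "c")
  fr <- buildForest(tr, percentage = 99, preset = 1L)
  fs <- forestStats(fr)
  expect_equal(fs$nodesPerBucketMean, 1)
  expect_true(all(fs$bstHeights == 1L))

  # shrinking preset: more buckets, fewer nodes per bucket, same forest
  tr2 <- buildSegmentTree(random_chrom_df(5, n = 120L), chrom = "c")
  sweep <- lapply(c(4096L, 1024L, 256L, 64L), function(ps)
    forestStats(buildForest(tr2, percentage = 1, preset = ps)))
  nb <- vapply(sweep, `[[`, numeric(1), "nBuckets")
  mn <- vapply(sweep, `[[`, numeric(1), "nodesPerBucketMean")
  expect_true(all(diff(nb) >= 0))
  expect_true(all(diff(mn) <= 0))
  expect_equal(length(unique(vapply(sweep, `[[`, numeric(1),
                                    "nForestNodes"))), 1L)

  # collision BST height never exceeds the source tree height
  for (seed in 1:10) {
    tr3 <- buildSegmentTree(random_chrom_df(seed, n = 150L), chrom = "c")
    for (pct in c(0.5, 1, 5, 10)) {
      fs3 <- forestStats(buildForest(tr3, percentage = pct, preset = 500L))
      expect_true(all(fs3$bstHeights <= fs3$sourceHeight))
    }
  }
})

test_that("raising the percentage cuts deeper and moves more intervals", {
  for (seed in c(2, 9, 21)) {
    tr <- buildSegmentTree(random_chrom_df(seed, n = 200L), chrom = "c")
    fs <- lapply(c(0.5, 1, 2, 5, 10, 30), function(p)
      forestStats(buildForest(tr, percentage = p, preset = 1000L)))
    moved <- vapply(fs, `[[`, numeric(1), "movedAttachments")
    cut_root <- vapply(fs, `[[`, numeric(1), "cutoffDepth")
    cut_leaf <- treeHeight(tr) - cut_root
    expect_true(all(diff(moved) >= 0))
    expect_true(all(diff(cut_root) >= 0))  # deeper cut from the root
    expect_true(all(diff(cut_leaf) <= 0))  # ...i.e. closer to the leaves
  }
})

test_that("an empty tree yields an empty forest and empty queries", {
  empty <- buildSegmentTree(data.frame(low = integer(0),
                                       high = integer(0),
                                       uid = character(0)), chrom = "c")
  fr <- buildForest(empty)
  expect_equal(nForestNodes(fr), 0L)
  expect_equal(nrow(queryInterval(fr, 1L, 100L)), 0L)
  expect_equal(lookupStart(fr, 1L, 100L)$branch, "none")
})
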