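mk_segs <- function(start, end, total, major, chrom = "chr1",
                    cluster = NULL, cellularity = NULL) {
  out <- data.frame(chrom = chrom, start = start, end = end,
                    total_cn = total, major_cn = major)
  if (!is.null(cluster)) out$cluster <- cluster
  if (!is.null(cellularity)) out$cellularity <- cellularity
  out
}

test_that("segment_accuracy applies the 75%-coverage exact-copy rule", {
  truth <- mk_segs(c(1, 1001, 3001, 6001), c(1000, 3000, 6000, 10000),
                   c(2, 3, 4, 2), c(1, 2, 2, 2))
  # identical predictions: accuracy 1
  expect_equal(segment_accuracy(truth, truth), 1)

  # one of four truth segments covered only 50%: accuracy 0.75
  pred <- truth
  pred$start[2] <- 2001  # covers 1000/2000 of truth segment 2
  expect_equal(segment_accuracy(truth, pred), 0.75)

  # exactly 75% coverage still counts
  pred2 <- truth
  pred2$start[2] <- 1501  # covers 1500/2000
  expect_equal(segment_accuracy(truth, pred2), 1)

  # correct coordinates but major_cn off by one everywhere: accuracy 0
  pred3 <- truth
  pred3$major_cn <- pmin(pred3$major_cn + 1, pred3$total_cn)
  pred3$major_cn[pred3$major_cn == truth$major_cn] <-
    truth$major_cn[pred3$major_cn == truth$major_cn] - 1
  expect_equal(segment_accuracy(truth, pred3), 0)

  # splitting a correct prediction in half defeats the single-segment rule,
  # unless one half still covers >= 75% of the truth segment
  t1 <- mk_segs(1, 10000, 3, 2)
  split_even <- mk_segs(c(1, 5001), c(5000, 10000), c(3, 3), c(2, 2))
  expect_equal(segment_accuracy(t1, split_even), 0)
  split_askew <- mk_segs(c(1, 8001), c(8000, 10000), c(3, 3), c(2, 2))
  expect_equal(segment_accuracy(t1, split_askew), 1)

  # order invariance and the empty-truth error
  expect_equal(segment_accuracy(truth[c(3, 1, 4, 2), ], pred), 0.75)
  expect_error(segment_accuracy(truth[0, ], pred), "empty")
  # neutral exclusion flag drops the (2,1) segment from the denominator
  expect_equal(segment_accuracy(truth, pred, include_neutral = FALSE), 2 / 3)
})

test_that("cellularity_metrics rank-matches and pools pairs", {
  # exact estimates
  m <- cellularity_metrics(list(c(0.3, 0.4), c(0.5)),
                           list(c(0.3, 0.4), c(0.5)))
  expect_equal(m$mae, 0)
  expect_equal(m$pearson_r, 1)

  # hand arithmetic on three pairs
  m2 <- cellularity_metrics(c(0.3, 0.4, 0.8), c(0.32, 0.41, 0.78))
  expect_equal(m2$mae, (0.02 + 0.01 + 0.02) / 3, tolerance = 1e-12)

  # a constant shift keeps r = 1 while MAE sees it
  m3 <- cellularity_metrics(c(0.2, 0.4, 0.6), c(0.25, 0.45, 0.65))
  expect_equal(m3$mae, 0.05, tolerance = 1e-12)
  expect_equal(m3$pearson_r, 1)

  # count mismatch: match from the largest down and flag the sample
  m4 <- cellularity_metrics(list(c(0.3, 0.4)), list(0.41))
  expect_equal(m4$pairs$truth, 0.4)
  expect_equal(m4$mae, 0.01, tolerance = 1e-12)
  expect_gt(m4$n_flagged, 0)

  # a single pooled pair leaves r undefined
  m5 <- cellularity_metrics(list(0.4), list(0.38))
  expect_true(is.na(m5$pearson_r))
  expect_equal(m5$mae, 0.02, tolerance = 1e-12)
})

test_that("purity_error is a plain absolute difference, batch-friendly", {
  expect_equal(purity_error(0.4, 0.4), 0)
  expect_equal(purity_error(0.4, 0.43), 0.03)
  v <- purity_error(seq(0.1, 0.9, by = 0.1), seq(0.9, 0.1, by = -0.1))
  expect_length(v, 9)
  expect_equal(mean(v), mean(abs(seq(0.1, 0.9, 0.1) - seq(0.9, 0.1, -0.1))))
})

test_that("cluster_concordance rank-matches cluster labels", {
  truth <- mk_segs(c(1, 5001), c(5000, 10000), c(3, 2), c(2, 2),
                   cellularity = c(0.3, 0.7))
  # perfect prediction: clusters 1 (0.3) and 2 (0.7) rank-match exactly
  pred <- mk_segs(c(1, 5001), c(5000, 10000), c(3, 2), c(2, 2),
                  cluster = c(1, 2), cellularity = c(0.31, 0.69))
  expect_equal(cluster_concordance(truth, pred, c(0.3, 0.7),
                                   c(0.31, 0.69)), 1)
  # everything assigned to one cluster when truth has two: half right
  pred1 <- pred
  pred1$cluster <- 2
  pred1$cellularity <- 0.69
  expect_equal(cluster_concordance(truth, pred1, c(0.3, 0.7),
                                   c(0.31, 0.69)), 0.5)
  # swapping the two labels yields the complement
  pred2 <- pred
  pred2$cellularity <- rev(pred2$cellularity)
  expect_equal(cluster_concordance(truth, pred2, c(0.3, 0.7),
                                   c(0.31, 0.69)), 0)
  # neutral truth segments are excluded (NA cellularity)
  truth_n <- rbind(truth, mk_segs(10001, 12000, 2, 1,
                                  cellularity = NA))
  expect_equal(cluster_concordance(truth_n, pred, c(0.3, 0.7),
                                   c(0.31, 0.69)), 1)
})
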