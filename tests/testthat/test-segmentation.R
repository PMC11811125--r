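# Weighted CBS and post-hoc smoothing.

test_that("label weights follow the gap rule with saturation", {
  w <- label_weights(c(0, 20000, 25000))
  expect_equal(w, c(1, 1, 0.5))          # first label uses its following gap
  expect_equal(label_weights(c(0, 10000))[2], 1)   # boundary counts as full
  expect_equal(label_weights(c(0, 2000))[2], 0.2)
  expect_error(label_weights(5), "2 labels")
  expect_error(label_weights(c(10, 10)), "increasing")
})

test_that("noiseless steps are segmented exactly", {
  tr <- toy_track(c(2, 10), run_len = 50)
  seg <- cbs_segment(tr, weights = rep(1, nrow(tr)))
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$start_label, c(1L, 51L))
  expect_equal(seg$mean, c(2, 10))

  const <- cbs_segment(toy_track(4, run_len = 60))
  expect_identical(nrow(const), 1L)

  three <- cbs_segment(toy_track(c(2, 8, 4), run_len = 30))
  expect_identical(three$start_label, c(1L, 31L, 61L))
  expect_equal(three$mean, c(2, 8, 4))
})

test_that("segmentation survives moderate noise", {
  set.seed(3)
  cn <- c(rep(2, 60), rep(12, 60)) + rnorm(120, 0, 0.4)
  tr <- label_track("chr1", seq_len(120) * 5000, 10 * pmax(cn, 0), pmax(cn, 0))
  seg <- cbs_segment(tr)
  expect_identical(nrow(seg), 2L)
  expect_lt(abs(seg$start_label[2] - 61L), 3L)
})

test_that("segments always partition the label range", {
  set.seed(4)
  for (rep in 1:5) {
    cn <- rep(sample(1:12, 4), each = 25) + rnorm(100, 0, 0.3)
    tr <- label_track("chr1", seq_len(100) * 4000, 10 * pmax(cn, 0), pmax(cn, 0))
    seg <- cbs_segment(tr)
    expect_identical(seg$start_label[1], 1L)
    expect_identical(seg$end_label[nrow(seg)], 100L)
    if (nrow(seg) > 1)
      expect_identical(seg$start_label[-1], seg$end_label[-nrow(seg)] + 1L)
  }
})

test_that("smoothing merges only short monotone middle segments", {
  # 3%-length middle of a monotone triplet merges into the CN-closer side
  tr <- toy_track(rep(c(2, 5, 9), times = c(40, 3, 57)), run_len = 1)
  seg <- cbs_segment(tr)
  sm <- smooth_segments(seg, tr)
  expect_identical(nrow(sm), 2L)
  # CN 5 merged into CN 2 side (|5-2| < |5-9|): first segment mean rises
  expect_gt(sm$mean[1], 2)
  expect_equal(sm$mean[2], 9)

  # non-monotone triplet unchanged
  tr2 <- toy_track(rep(c(2, 9, 4), times = c(30, 3, 67)), run_len = 1)
  seg2 <- cbs_segment(tr2)
  sm2 <- smooth_segments(seg2, tr2)
  expect_identical(nrow(sm2), nrow(seg2))

  # single segment unchanged
  tr3 <- toy_track(5, run_len = 30)
  expect_identical(nrow(smooth_segments(cbs_segment(tr3), tr3)), 1L)
})

test_that("smoothing is idempotent and never adds segments", {
  set.seed(9)
  for (rep in 1:5) {
    cn <- rep(sample(1:10, 5), times = sample(3:40, 5))
    tr <- label_track("chr1", seq_along(rep(cn, 1)) * 5000, 10 * cn, cn)
    seg <- cbs_segment(tr)
    s1 <- smooth_segments(seg, tr)
    expect_lte(nrow(s1), nrow(seg))
    s2 <- smooth_segments(s1, tr)
    expect_identical(as.data.frame(s1), as.data.frame(s2))
  }
})
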