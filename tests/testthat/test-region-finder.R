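# Candidate-label selection and region linkage.

make_fb <- function(chrom, pos, side, ids) {
  foldback_set(chrom, pos, pos, side, list(ids))
}

test_that("selection requires both amplification and foldback excess", {
  tr <- label_track("chr1", (1:100) * 1e4, rep(50, 100),
                    c(rep(1, 90), rep(5, 10)))
  fb <- make_fb("chr1", 95e4, "right", paste0("m", 1:4))
  sel <- select_labels(tr, fb)
  expect_true(length(sel) >= 1)
  expect_true(all(tr$cn[sel] > 3))

  # CN exactly 3 is rejected regardless of foldbacks (strict >3)
  tr$cn[95] <- 3
  sel2 <- select_labels(tr, fb)
  expect_false(95L %in% sel2)

  # amplified but without foldbacks: rejected
  tr3 <- label_track("chr1", (1:50) * 1e4, rep(50, 50), rep(10, 50))
  expect_length(select_labels(tr3, foldback_set()), 0)
})

test_that("directional assignment keeps boundary folds on their segment", {
  # labels at 10k..100k; a right fold exactly at 50,000 belongs to the
  # label at or before it, a left fold there to the label at or after
  tr <- label_track("chr1", (1:10) * 1e4, rep(10, 10), rep(5, 10))
  fbr <- make_fb("chr1", 5e4, "right", c("a", "b"))
  fbl <- make_fb("chr1", 5e4, "left", c("c"))
  mr <- bfbscope:::assign_foldbacks(tr, fbr)
  ml <- bfbscope:::assign_foldbacks(tr, fbl)
  expect_true(all(tr$pos[mr$label] <= 5e4))
  expect_true(all(tr$pos[ml$label] >= 5e4))
})

test_that("linkage follows the distance / copy-number disjunction", {
  base <- function(cns, gap) {
    pos <- c(1e6, 1e6 + gap)
    label_track("chr1", pos, rep(50, 2), cns)
  }
  link2 <- function(cns, gap) {
    tr <- base(cns, gap)
    nrow(link_and_cluster(1:2, tr))
  }
  expect_identical(link2(c(5, 6), 1.2e6), 1L)   # D < 1.5 Mbp
  expect_identical(link2(c(8, 8), 2.0e6), 1L)   # E = 8 > 7
  expect_identical(link2(c(5, 6), 2.0e6), 2L)   # neither
})

test_that("regions partition the selected labels and stay sorted", {
  set.seed(5)
  pos <- sort(sample(1:5e7, 300))
  tr <- label_track("chr1", pos, rep(50, 300), sample(4:9, 300, TRUE))
  sel <- sample(300, 80)
  reg <- link_and_cluster(sel, tr)
  members <- unlist(reg$labels)
  expect_setequal(members, sel)
  expect_identical(anyDuplicated(members), 0L)
  expect_true(all(diff(reg$start) > 0))
  expect_true(all(reg$end > reg$start))
})

test_that("loosening thresholds never drops a selected label", {
  set.seed(6)
  tr <- label_track("chr1", (1:200) * 1e4, rpois(200, 50),
                    sample(c(1, 2, 5, 8), 200, TRUE))
  ids <- split(paste0("m", 1:300), sample(60, 300, TRUE))
  at <- sample(tr$pos, length(ids))
  fb <- foldback_set(rep("chr1", length(ids)), pos_a = at, pos_b = at,
                     side = sample(c("left", "right"), length(ids), TRUE),
                     molecules = unname(ids))
  strict <- select_labels(tr, fb, cn_min = 4, fb_excess = 1.5)
  loose <- select_labels(tr, fb, cn_min = 3, fb_excess = 1.1)
  expect_true(all(strict %in% loose))
})
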