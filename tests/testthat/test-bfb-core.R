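# BFB string grammar: cycle application, induced vectors, membership.

test_that("the three-cycle derivation reproduces the canonical rearrangement", {
  s <- parse_bfb("1+2+3+")
  s1 <- apply_cycle(s, 5)
  expect_identical(format(s1), "1+2+3+3-2-")
  s2 <- apply_cycle(s1, 6)
  expect_identical(format(s2), "1+2+3+3-2-2+")
  s3 <- apply_cycle(s2, 11)
  expect_identical(format(s3), "1+2+3+3-2-2+2-2+3+3-2-")
  expect_identical(count_vector(s3, 4), c(1L, 6L, 4L, 0L))
  fb <- foldback_vectors(s3, 4)
  expect_identical(fb$L, c(0L, 2L, 0L, 0L))
  expect_identical(fb$R, c(0L, 1L, 2L, 0L))
})

test_that("apply_cycle handles degenerate and boundary break lengths", {
  expect_identical(format(apply_cycle("1+", 2)), "1+1-")
  # break_len <= |s| is a pure loss: the prefix
  expect_identical(format(apply_cycle("1+2+3+", 2)), "1+2+")
  expect_error(apply_cycle("1+2+", 5), "break_len")
  expect_error(apply_cycle("1+2+", 0), "break_len")
})

test_that("count and foldback vectors agree with direct tabulation", {
  expect_identical(count_vector("1+2+3+", 4), c(1L, 1L, 1L, 0L))
  expect_identical(count_vector("1+1-", 1), 2L)
  fb <- foldback_vectors("1+2+3+", 3)
  expect_identical(fb$L, integer(3))
  expect_identical(fb$R, integer(3))
  fb <- foldback_vectors("1+1-", 1)
  expect_identical(fb$L, 0L)
  expect_identical(fb$R, 1L)
})

test_that("BFB membership separates derivable from ladder-mimicking strings", {
  expect_true(is_bfb_string("1+2+3+3-2-2+2-2+3+3-2-"))
  expect_false(is_bfb_string("1+2+2-2+2-2+2-3-3+3-3+"))
  expect_true(is_bfb_string("1+"))
  expect_true(is_bfb_string("1+2+3+"))
})

test_that("bfb_string validates well-formedness", {
  expect_error(bfb_string(integer(), integer()), "nonempty")
  expect_error(bfb_string(c(2L, 1L), c(1L, 1L)), "start with")
  expect_error(bfb_string(c(1L, 3L), c(1L, 1L)), "prefix")
  expect_error(parse_bfb("1+x2-"), "parse")
})

test_that("cycle closure: apply_cycle output stays in the BFB language", {
  set.seed(11)
  for (rep in 1:25) {
    s <- bfb_string(1:3, rep(1L, 3))
    for (step in 1:4) {
      s <- apply_cycle(s, sample.int(2L * length(s), 1L))
      expect_true(is_bfb_string(s))
    }
  }
})

test_that("full-length cycles double every segment count", {
  set.seed(12)
  for (rep in 1:10) {
    s <- bfb_string(1:3, rep(1L, 3))
    for (step in 1:3) s <- apply_cycle(s, length(s) + sample.int(length(s), 1L))
    doubled <- apply_cycle(s, 2L * length(s))
    expect_identical(count_vector(doubled, 3), 2L * count_vector(s, 3))
  }
})

test_that("membership agrees with the breadth-first oracle on short strings", {
  reach <- prefix_closure(bfs_reachable(2, 8))
  # enumerate all well-formed strings over 2 segments up to length 6
  alphabet <- c(1L, -1L, 2L, -2L)
  todo <- list(c(1L))
  checked <- 0L
  while (length(todo)) {
    v <- todo[[1L]]; todo <- todo[-1L]
    segs <- abs(v); dirs <- sign(v)
    if (identical(sort(unique(segs)), seq_len(max(segs)))) {
      s <- bfb_string(segs, dirs)
      expect_identical(is_bfb_string(s), format(s) %in% reach,
                       info = format(s))
      checked <- checked + 1L
    }
    if (length(v) < 6L)
      for (a in alphabet) todo[[length(todo) + 1L]] <- c(v, a)
  }
  expect_gt(checked, 500L)
})

test_that("enumeration finds exact architectures and ranks by discrepancy", {
  cand <- enumerate_architectures(c(1, 6, 4, 0))
  expect_identical(cand[[1L]]$copy_discrepancy, 0)
  expect_identical(cand[[1L]]$C, c(1L, 6L, 4L, 0L))
  expect_true(all(diff(vapply(cand, `[[`, 0, "copy_discrepancy")) >= 0))

  expect_identical(enumerate_architectures(c(1))[[1L]]$string, "1+")
  c12 <- enumerate_architectures(c(1, 2), max_cycles = 3)
  expect_identical(c12[[1L]]$copy_discrepancy, 0)
  expect_true(is_bfb_string(c12[[1L]]$string))

  expect_error(enumerate_architectures(c(0, 0)), "positive")
  expect_error(enumerate_architectures(numeric()), "positive")
})

test_that("every enumerated candidate is internally consistent", {
  for (target in list(c(1, 6, 4, 0), c(2, 4), c(3, 5, 2))) {
    cand <- enumerate_architectures(target)
    for (x in cand) {
      n <- length(x$C)
      expect_true(is_bfb_string(x$string))
      expect_identical(count_vector(x$string, n), x$C)
      fb <- foldback_vectors(x$string, n)
      expect_identical(fb$L, x$L)
      expect_identical(fb$R, x$R)
      # telomeric contiguity
      nz <- which(x$C > 0)
      expect_identical(nz, seq_len(length(nz)))
    }
  }
})

test_that("enumeration decision agrees with the oracle for small vectors", {
  # all vectors over 3 segments with entries <= 4: exact architecture exists
  # iff the BFS closure contains a string with that count vector
  cmax <- c(4L, 4L, 4L)
  reach <- bfs_reachable(3, sum(cmax), cmax = cmax)
  seen_vec <- unique(vapply(reach, function(s)
    paste(count_vector(s, 3), collapse = ","), ""))
  grid <- expand.grid(a = 0:4, b = 0:4, c = 0:4)
  for (i in seq_len(nrow(grid))) {
    v <- as.integer(grid[i, ])
    if (all(v == 0L)) next
    if (any(diff(v > 0) > 0)) next       # interior zeros cannot be exact
    cand <- enumerate_architectures(v, max_candidates = 4)
    exact <- length(cand) > 0 && cand[[1L]]$copy_discrepancy == 0
    expect_identical(exact, paste(v, collapse = ",") %in% seen_vec,
                     info = paste(v, collapse = ","))
  }
})
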