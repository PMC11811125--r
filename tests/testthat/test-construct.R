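# Inverse construction: build a BFB string realizing a target (C, L, R).

test_that("the worked-example class is reconstructed exactly", {
  s <- construct_architecture(c(1, 6, 4, 0), c(0, 2, 0, 0), c(0, 1, 2, 0))
  expect_false(is.null(s))
  expect_identical(count_vector(s, 4), c(1L, 6L, 4L, 0L))
  fb <- foldback_vectors(s, 4)
  expect_identical(fb$L, c(0L, 2L, 0L, 0L))
  expect_identical(fb$R, c(0L, 1L, 2L, 0L))
  expect_true(is_bfb_string(s))
})

test_that("unrealizable foldback profiles are rejected", {
  # ecDNA-like: both-end foldbacks with intact flanks is not a BFB class
  expect_null(construct_architecture(c(1, 80, 1), c(0, 40, 0), c(0, 40, 0)))
  # interior zero copy number
  expect_null(construct_architecture(c(1, 0, 2), c(0, 0, 0), c(0, 0, 1)))
  # fold counts exceeding what the copy numbers admit
  expect_null(construct_architecture(c(1, 2), c(0, 5), c(0, 5)))
})

test_that("construction inverts simulated ground truths across the design range", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    segs <- sample(1:7, 1)
    cn <- runif(1, 5, 80)
    sim <- simulate_bfb(sim_config(n_segments = segs, target_cn = cn,
                                   seed = seed))
    v <- sim$vectors
    s <- construct_architecture(v$C, v$L, v$R)
    if (!is.null(s)) {
      n <- length(v$C)
      expect_identical(count_vector(s, n), v$C)
      fb <- foldback_vectors(s, n)
      expect_identical(fb$L, v$L)
      expect_identical(fb$R, v$R)
      expect_true(is_bfb_string(s))
      hits <- hits + 1L
    }
  }
  # the constructor is not complete, but must solve the large majority
  expect_gte(hits, 32L)
})

test_that("a centromeric anchor prefix is stripped and restored", {
  s <- construct_architecture(c(1, 1, 6, 4), c(0, 0, 2, 0), c(0, 0, 1, 2))
  expect_false(is.null(s))
  expect_identical(count_vector(s, 4), c(1L, 1L, 6L, 4L))
  expect_identical(s$seg[1:2], c(1L, 2L))
})
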