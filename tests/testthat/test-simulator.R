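# Simulators and the rendering layer.

test_that("zero cycles leave the arm unrearranged", {
  sim <- simulate_bfb(sim_config(n_cycles = 0, n_segments = 4, seed = 1))
  expect_identical(sim$vectors$C, rep(1L, 4))
  expect_identical(sim$vectors$L, rep(0L, 4))
  expect_identical(sim$vectors$R, rep(0L, 4))
  expect_identical(format(sim$string), "1+2+3+4+")
})

test_that("simulation is reproducible and produces valid structures", {
  a <- simulate_bfb(sim_config(tier = "simple", n_cycles = 3, seed = 7))
  b <- simulate_bfb(sim_config(tier = "simple", n_cycles = 3, seed = 7))
  expect_identical(format(a$string), format(b$string))
  expect_identical(a$structure$segments, b$structure$segments)

  expect_true(is_bfb_string(a$string))
  expect_gte(sum(a$vectors$L) + sum(a$vectors$R), 1L)

  # recomputed vectors match the final structure
  n <- nrow(a$arm)
  expect_identical(count_vector(a$string, n), a$vectors$C)
  fb <- foldback_vectors(a$string, n)
  expect_identical(fb$L, a$vectors$L)
  expect_identical(fb$R, a$vectors$R)
})

test_that("targeted simulation approaches the requested mean copy number", {
  for (seed in 1:6) {
    sim <- simulate_bfb(sim_config(n_segments = 3, target_cn = 30,
                                   seed = seed))
    mean_cn <- mean(sim$vectors$C[1:3])
    expect_gt(mean_cn, 15)
    expect_lt(mean_cn, 60)
  }
})

test_that("noiseless sharp rendering reproduces the structure exactly", {
  sim <- simulate_bfb(sim_config(tier = "simple", n_segments = 3,
                                 target_cn = 8, seed = 9))
  rc <- render_config(z1 = 50, noise = "none", dropout = 0, seed = 10)
  obs <- render_observed(sim, rc)
  segs <- sim$structure$segments
  for (i in seq_len(nrow(segs))) {
    labs <- obs$track$pos >= segs$start[i] & obs$track$pos < segs$end[i]
    expect_true(all(obs$track$cn[labs] == segs$cn[i]))
  }
  # foldback support = z1 x multiplicity
  jn <- sim$structure$junctions
  expect_identical(nrow(obs$foldbacks), nrow(jn))
  sizes <- vapply(obs$foldbacks$molecules, length, 0L)
  expect_identical(sort(sizes), sort(as.integer(50 * jn$multiplicity)))
})

test_that("Poisson rendering has the right coverage scale", {
  sim <- simulate_bfb(sim_config(tier = "simple", n_segments = 1,
                                 n_cycles = 1, seed = 11))
  obs <- render_observed(sim, render_config(z1 = 40, seed = 12))
  two <- obs$track$pos >= sim$arm$start[1] & obs$track$pos < sim$arm$end[1]
  expect_equal(mean(obs$track$coverage[two]), 40 * 2, tolerance = 0.1)
  # Z1 recovered within 10%
  expect_lt(abs(estimate_z1(obs$track) - 40) / 40, 0.1)
})

test_that("gradual boundaries produce intermediate copy numbers", {
  sim <- simulate_bfb(sim_config(tier = "simple", n_segments = 2,
                                 target_cn = 20, seed = 13))
  sharp <- render_observed(sim, render_config(noise = "none", dropout = 0,
                                              boundary_mode = "sharp", seed = 14))
  grad <- render_observed(sim, render_config(noise = "none", dropout = 0,
                                             boundary_mode = "gradual",
                                             ramp_labels = 5, seed = 14))
  expect_identical(sharp$track$pos, grad$track$pos)
  lv_sharp <- sort(unique(sharp$track$cn))
  off_grid <- setdiff(round(grad$track$cn, 6), lv_sharp)
  expect_gt(length(off_grid), 0)
})

test_that("negative simulators produce their defining signatures", {
  plain <- simulate_negative("ecdna", params = list(dup_inv = "none"),
                             seed = 15)
  expect_identical(nrow(plain$structure$junctions), 0L)
  obs <- render_observed(plain, render_config(seed = 16))
  expect_length(select_labels(obs$track, obs$foldbacks), 0)

  dup <- simulate_negative("ecdna",
                           params = list(n_segments = 1, dup_inv = "both"),
                           seed = 17)
  expect_setequal(dup$structure$junctions$side, c("left", "right"))

  a <- simulate_negative("chromothripsis", seed = 18)
  b <- simulate_negative("chromothripsis", seed = 18)
  expect_identical(a$structure$segments, b$structure$segments)
  expect_error(simulate_negative("banana"), "arg")
})

test_that("a tiny benchmark separates a positive from a negative and is reproducible", {
  bm1 <- run_benchmark(n_pos = 2, n_neg = 2,
                       params = bfb_params(gibbs_iters = 150),
                       render = render_config(noise = "none", dropout = 0),
                       seg_range = c(2L, 3L), cn_range = c(8, 20),
                       mix_boundaries = FALSE, seed = 19)
  expect_identical(nrow(bm1$cases), 4L)
  pos_scores <- bm1$cases$score[bm1$cases$label == "positive"]
  neg_scores <- bm1$cases$score[bm1$cases$label == "negative"]
  expect_lt(min(pos_scores), min(neg_scores))
  expect_gte(bm1$max_f1, 0.99)

  bm2 <- run_benchmark(n_pos = 2, n_neg = 2,
                       params = bfb_params(gibbs_iters = 150),
                       render = render_config(noise = "none", dropout = 0),
                       seg_range = c(2L, 3L), cn_range = c(8, 20),
                       mix_boundaries = FALSE, seed = 19)
  expect_identical(bm1$cases, bm2$cases)
})
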