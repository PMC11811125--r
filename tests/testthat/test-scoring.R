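# Scoring: Z1, observed foldback copy numbers, the two discrepancies, the
# final score, Gibbs contracts, classification, calibration.

test_that("Z1 is total coverage over total copy number", {
  expect_equal(estimate_z1(label_track("chr1", c(0, 5e3, 1e4),
                                       c(20, 20, 40), c(2, 2, 4))), 10)
  expect_equal(estimate_z1(label_track("chr1", 0, 7, 1)), 7)
  expect_error(estimate_z1(label_track("chr1", c(0, 1e3), c(0, 0), c(0, 0))),
               "undefined")
})

test_that("observed foldback copy numbers deduplicate molecules by union", {
  fb <- foldback_set(rep("chr1", 2), c(1e4, 2e4), c(1e4, 2e4),
                     c("right", "right"),
                     list(paste0("m", 1:5), paste0("m", 1:5)))
  ob <- observed_foldback_cn(fb, z1 = 5)
  expect_equal(ob[["R"]], 1)            # union of identical sets, not sum
  expect_equal(ob[["L"]], 0)

  fb2 <- foldback_set("chr1", 1e4, 1e4, "right", list(paste0("m", 1:30)))
  expect_equal(observed_foldback_cn(fb2, 10)[["R"]], 3)
  expect_equal(observed_foldback_cn(foldback_set(), 10)[["R"]], 0)
})

test_that("the model discrepancy combines copy, foldback and penalty terms", {
  perfect <- delta_model(list(C_o = c(1, 6, 4, 0), L_o = c(0, 2, 0, 0),
                              R_o = c(0, 1, 2, 0)),
                         list(C = c(1L, 6L, 4L, 0L), L = c(0L, 2L, 0L, 0L),
                              R = c(0L, 1L, 2L, 0L)))
  expect_equal(perfect$value, 0)
  expect_identical(perfect$F, 0L)

  copy_only <- delta_model(list(C_o = 5, L_o = 0, R_o = 0),
                           list(C = 4L, L = 0L, R = 0L))
  expect_equal(copy_only$value, 0.25)

  fb_case <- delta_model(list(C_o = 2, L_o = 1, R_o = 0),
                         list(C = 2L, L = 0L, R = 0L),
                         bfb_params(alpha = 7, p1 = 1))
  expect_equal(fb_case$value, 8)        # 7 * 1 + 1 * 1
  expect_identical(fb_case$F, 1L)

  # predicted-but-unobserved foldbacks incur no F penalty
  missed <- delta_model(list(C_o = 2, L_o = 0, R_o = 0),
                        list(C = 2L, L = 1L, R = 0L))
  expect_identical(missed$F, 0L)

  expect_error(delta_model(list(C_o = c(1, 2), L_o = c(0, 0), R_o = c(0, 0)),
                           list(C = 1L, L = 0L, R = 0L)),
               "segment counts")
})

test_that("the data discrepancy sums per-segment mean deviations", {
  expect_equal(delta_data(c(5, 5, 5), rep(1L, 3), 5), 0)
  expect_equal(delta_data(c(4, 5, 6), rep(1L, 3), 5), 2 / 3)
  expect_equal(delta_data(c(4, 6, 1, 2), c(1L, 1L, 2L, 2L), c(5, 1.5)),
               1 + 0.5)
  expect_error(delta_data(c(1, 2), c(1L, 1L), c(1, 2)), "least one label")
})

test_that("the score normalises by the segment-count power", {
  expect_equal(bfb_score(0, 0, 5), 0)
  expect_equal(bfb_score(0.5, 0.5, 2), 1 / 2^0.9)
  expect_equal(bfb_score(1, 0, 1), 1)
  expect_equal(bfb_score(1, 1, 3, bfb_params(c = 1.2)), 2 / 3^1.2)
})

test_that("Gibbs refinement is deterministic under a seed and never worsens the start", {
  sim <- simulate_bfb(sim_config(tier = "simple", n_segments = 3,
                                 target_cn = 12, seed = 31))
  obs <- render_observed(sim, render_config(seed = 32))
  sl <- bfbscope:::region_slice(obs$track, obs$foldbacks,
                                list(chrom = "chr1", start = 1e7, end = 1.1e7),
                                3e5, 5e4)
  params <- bfb_params(seed = 33, gibbs_iters = 200)
  run1 <- local({ set.seed(33); gibbs_refine(sl$track, sl$foldbacks,
                                             params = params) })
  run2 <- local({ set.seed(33); gibbs_refine(sl$track, sl$foldbacks,
                                             params = params) })
  expect_identical(run1$breakdown, run2$breakdown)
  expect_identical(run1$latent, run2$latent)

  # monotone improvement: the returned score cannot exceed the initial one
  init <- local({ set.seed(33); gibbs_refine(sl$track, sl$foldbacks,
                                             params = bfb_params(seed = 33,
                                                                 gibbs_iters = 0)) })
  expect_lte(run1$breakdown$score, init$breakdown$score)
})

test_that("classification thresholds and filters behave as specified", {
  # noiseless positive: perfect reconstruction
  sim <- simulate_bfb(sim_config(tier = "simple", n_segments = 2,
                                 target_cn = 10, seed = 41))
  obs <- render_observed(sim, render_config(noise = "none", dropout = 0,
                                            seed = 42))
  fit <- bfb_fit(obs$track, obs$foldbacks, params = bfb_params(seed = 43))
  expect_identical(fit$classification, "BFB_positive")
  expect_lt(fit$score, 1e-9)
  expect_true(is_bfb_string(fit$string))

  # single amplified segment with both-side foldbacks and intact flanks
  neg <- simulate_negative("ecdna",
                           params = list(n_segments = 1, dup_inv = "both",
                                         cn = 40), seed = 44)
  obs2 <- render_observed(neg, render_config(seed = 45))
  fit2 <- bfb_fit(obs2$track, obs2$foldbacks, params = bfb_params(seed = 46))
  expect_identical(fit2$classification, "filtered_ecDNA_like")
  expect_equal(fit2$score, 4)

  # a region without any selected label is filtered with the sentinel
  tr <- label_track("chr1", (1:50) * 1e4, rep(50, 50), rep(1, 50))
  fit3 <- classify_amplicon(list(chrom = "chr1", start = 1e5, end = 3e5),
                            tr, foldback_set(), bfb_params(seed = 47))
  expect_identical(fit3$classification, "filtered")
  expect_equal(fit3$score, 4)
})

test_that("coverage rescaling leaves the score invariant", {
  sim <- simulate_bfb(sim_config(tier = "simple", n_segments = 2,
                                 target_cn = 9, seed = 51))
  obs1 <- render_observed(sim, render_config(z1 = 100, noise = "none",
                                             dropout = 0, seed = 52))
  obs2 <- render_observed(sim, render_config(z1 = 200, noise = "none",
                                             dropout = 0, seed = 52))
  f1 <- bfb_fit(obs1$track, obs1$foldbacks, params = bfb_params(seed = 53))
  f2 <- bfb_fit(obs2$track, obs2$foldbacks, params = bfb_params(seed = 53))
  expect_equal(f1$score, f2$score, tolerance = 1e-6)
})

test_that("grid calibration maximises F1 with deterministic tie-breaks", {
  cases <- data.frame(
    label = rep(c("positive", "negative"), each = 4),
    copy_term = c(rep(0.1, 4), rep(3, 4)),
    euclid = c(rep(0.05, 4), rep(2, 4)),
    F = c(rep(0L, 4), rep(2L, 4)),
    delta_data = c(rep(0.2, 4), rep(2, 4)),
    n = rep(3L, 8))
  best <- calibrate_params(cases, p1_grid = 0:2, alpha_grid = c(3, 7),
                           c_grid = c(0.9, 1.1))
  expect_equal(best$f1, 1)
  expect_equal(best$p1, 0)              # smallest p1 among perfect grid points
  expect_equal(best$alpha, 3)

  expect_error(calibrate_params(within(cases, label <- "positive")),
               "at least one")
})
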