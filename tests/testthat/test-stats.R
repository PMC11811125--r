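# Fragile-region window test, break-dispersion test, foldback distances.

test_that("the composition-null p-value matches exhaustive enumeration", {
  # s = 2 breaks into w = 2 windows: compositions (0,2), (1,1), (2,0);
  # max >= 2 in two of the three
  expect_equal(fragile_region_pvalue(2, 2, 2), 2 / 3)
  # exhaustive check for all (s, t_m) with s <= 6, w = 3
  compositions <- function(s, w) {
    if (w == 1) return(matrix(s, 1))
    out <- NULL
    for (first in 0:s)
      out <- rbind(out, cbind(first, compositions(s - first, w - 1)))
    out
  }
  for (s in 1:6) {
    comp <- compositions(s, 3)
    for (t_m in 1:s) {
      expect_equal(fragile_region_pvalue(s, t_m, 3),
                   mean(apply(comp, 1, max) >= t_m),
                   tolerance = 1e-12, info = paste(s, t_m))
    }
  }
})

test_that("boundary cases are handled explicitly", {
  expect_equal(fragile_region_pvalue(5, 6, 10), 0)     # impossible event
  expect_equal(fragile_region_pvalue(5, 0, 10), 1)
  expect_equal(fragile_region_pvalue(30, 1, 10), 1)    # some window has >= 1
})

test_that("the recurrent-amplification case evaluates near 0.039", {
  p <- fragile_region_pvalue(30, 16, 10)
  expect_equal(p, 0.0386, tolerance = 1e-2)
  # cross-check against the multinomial Monte-Carlo placement null: the
  # composition null is flatter, so only order-of-magnitude agreement is
  # expected; compare instead against a composition sampler
  set.seed(101)
  draws <- replicate(40000, {
    cuts <- sort(sample.int(30 + 10 - 1, 10 - 1))
    max(diff(c(0, cuts, 40)) - 1)
  })
  mc <- mean(draws >= 16)
  se <- sqrt(mc * (1 - mc) / length(draws))
  expect_lt(abs(p - mc), 3 * se + 1e-6)
})

test_that("the closed form tracks a Monte-Carlo composition sampler", {
  set.seed(102)
  for (case in 1:20) {
    s <- sample(5:40, 1); w <- sample(2:12, 1)
    t_m <- sample(seq_len(s), 1)
    p <- fragile_region_pvalue(s, t_m, w)
    draws <- replicate(4000, {
      cuts <- if (w > 1) sort(sample.int(s + w - 1, w - 1)) else integer()
      max(diff(c(0, cuts, s + w)) - 1)
    })
    mc <- mean(draws >= t_m)
    se <- sqrt(max(mc * (1 - mc), 1e-6) / length(draws))
    expect_lt(abs(p - mc), 3 * se + 0.01, label = paste(s, t_m, w))
  }
})

test_that("p-values decrease in the maximum window count", {
  p <- vapply(1:20, function(t) fragile_region_pvalue(20, t, 10), 0)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("the dispersion test separates random from clustered breaks", {
  genome <- data.frame(chrom = "chr1", start = 0, end = 5e9)
  set.seed(103)
  random_breaks <- data.frame(chrom = "chr1",
                              pos = runif(300, 0, 5e9))
  r <- genome_bin_test(random_breaks, genome, bin_size = 5e6)
  clustered <- data.frame(chrom = "chr1",
                          pos = runif(300, 0, 2e6))   # all in one bin
  cl <- genome_bin_test(clustered, genome, bin_size = 5e6)
  expect_lt(r$statistic, cl$statistic)
  # with the rate refitted from the clustered data the discrete statistic
  # is bounded by the zero-class gap (~1 - exp(-lambda)); near-maximal
  # clustering still dwarfs the null statistic
  expect_gt(cl$statistic, 0.2)
  expect_gt(cl$statistic, 5 * r$statistic)

  # under the null the statistic is usually small
  rejections <- 0L
  for (rep in 1:20) {
    b <- data.frame(chrom = "chr1", pos = runif(500, 0, 5e9))
    res <- genome_bin_test(b, genome, bin_size = 5e6, nsim = 200)
    if (res$p_value <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)

  deg <- genome_bin_test(data.frame(chrom = "chr1", pos = 1e6),
                         data.frame(chrom = "chr1", start = 0, end = 5e6))
  expect_equal(deg$p_value, 1)
  expect_error(genome_bin_test(random_breaks, genome[0, ]), "empty")
})

test_that("foldback distance summaries report the long-tail fraction", {
  fb <- foldback_set(rep("chr1", 3), c(1e4, 2e4, 3e4),
                     c(1e4 + 500, 2e4 + 1500, 3e4 + 2500),
                     rep("right", 3), as.list(paste0("m", 1:3)))
  st <- foldback_distance_stats(fb)
  expect_equal(st$distances, c(500, 1500, 2500))
  expect_equal(st$fraction_gt_cutoff, 2 / 3)
  expect_equal(st$cdf(1500), 2 / 3)

  palindromic <- foldback_set("chr1", 1e4, 1e4, "left", list("m1"))
  expect_equal(foldback_distance_stats(palindromic)$fraction_gt_cutoff, 0)
  expect_error(foldback_distance_stats(foldback_set()), "empty")
})

test_that("fold-region deletions yield the expected distance tail", {
  set.seed(104)
  ds <- c()
  for (seed in 1:12) {
    sim <- simulate_bfb(sim_config(tier = "intermediate", n_segments = 3,
                                   target_cn = 15, fold_del_prob = 1,
                                   fold_del_mean = 2000, seed = seed))
    obs <- render_observed(sim, render_config(seed = seed))
    if (nrow(obs$foldbacks))
      ds <- c(ds, foldback_distance_stats(obs$foldbacks)$distances)
  }
  # |Exp(2k) - Exp(2k)| is Exp(2k): P(d > 1000) = exp(-1/2) ~ 0.61
  expect_gt(mean(ds > 1000), 0.5)
})
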