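# Auxiliary statistics: fragile-region window test, break-dispersion test,
# foldback-distance summaries.

#' Fragile-region window test
#'
#' Given `s` BFB breaks in a region divided into `w` windows, with at most
#' `t_m` breaks observed in any single window, computes the probability that
#' a uniformly random composition of `s` breaks into `w` ordered windows
#' puts at least `t_m` breaks into some window.  The null is uniform over
#' the `choose(s + w - 1, w - 1)` compositions; inclusion-exclusion over the
#' windows that exceed the bound gives
#' \deqn{p = \sum_{m \ge 1} (-1)^{m+1} \binom{w}{m}
#'       \binom{s - m t_m + w - 1}{w - 1} / \binom{s + w - 1}{w - 1}.}
#' A small p-value indicates preferential clustering of the initiating
#' breaks (a fragile site); `t_m = 0` returns 1 and `t_m > s` returns 0.
#'
#' @param s total number of BFB breaks in the region.
#' @param t_m maximum number of breaks in a single window.
#' @param w number of windows (default 10).
#' @param method `"exact"` (inclusion-exclusion, default) or
#'   `"multinomial"` (Monte-Carlo under multinomial placement, for
#'   comparison).
#' @param nsim Monte-Carlo draws for the multinomial method.
#' @return p-value in `[0, 1]`.
#' @examples
#' fragile_region_pvalue(2, 2, 2)    # 2/3
#' fragile_region_pvalue(30, 16, 10) # ~0.0386
#' @export
fragile_region_pvalue <- function(s, t_m, w = 10, method = c("exact", "multinomial"),
                                  nsim = 1e5) {
  method <- match.arg(method)
  stopifnot(s >= 0, t_m >= 0, w >= 1)
  if (t_m == 0) return(1)
  if (t_m > s) return(0)
  if (method == "multinomial") {
    draws <- stats::rmultinom(nsim, s, rep(1 / w, w))
    return(mean(apply(draws, 2L, max) >= t_m))
  }
  denom <- lchoose(s + w - 1, w - 1)
  mm <- seq_len(floor(s / t_m))
  terms <- (-1)^(mm + 1) * exp(lchoose(w, mm) +
                                 lchoose(s - mm * t_m + w - 1, w - 1) - denom)
  min(1, max(0, sum(terms)))
}

#' Dispersion test for break locations over genome bins
#'
#' Partitions the genome into fixed-size bins, counts breaks per bin, and
#' compares the empirical count distribution against a Poisson fitted by
#' the mean with a two-tailed KS statistic.  Random (Poisson-like) break
#' placement gives a small statistic; clustering inflates it.  Because the
#' counts are discrete and the rate is estimated from the same data, the
#' p-value is calibrated by parametric simulation (`nsim` Poisson
#' replicates of the fitted model, each refitted by its own mean) rather
#' than by the continuous KS null.
#'
#' @param breaks data.frame with `chrom`, `pos` (one row per break).
#' @param genome data.frame with `chrom`, `start`, `end` intervals to bin.
#' @param bin_size bin width in bp (default 5e6).
#' @param nsim parametric-bootstrap replicates for the p-value.
#' @return `list(statistic, p_value, counts, lambda)`.
#' @export
genome_bin_test <- function(breaks, genome, bin_size = 5e6, nsim = 500) {
  if (nrow(genome) == 0L) stop("empty genome definition")
  if (nrow(breaks) == 0L) stop("at least one break is required")
  counts <- integer()
  for (g in seq_len(nrow(genome))) {
    edges <- seq(genome$start[g], genome$end[g], by = bin_size)
    if (edges[length(edges)] < genome$end[g])
      edges <- c(edges, genome$end[g])
    p <- breaks$pos[breaks$chrom == genome$chrom[g]]
    p <- p[p >= genome$start[g] & p < genome$end[g]]
    counts <- c(counts, tabulate(findInterval(p, edges), nbins = length(edges) - 1L))
  }
  lambda <- mean(counts)
  ks_stat <- function(x, lam) {
    xs <- sort(unique(x))
    ec <- stats::ecdf(x)(xs)
    max(abs(ec - stats::ppois(xs, lam)),
        abs(c(0, ec[-length(ec)]) - stats::ppois(xs - 1L, lam)))
  }
  if (length(counts) < 2L) {
    return(list(statistic = 0, p_value = 1, counts = counts,
                lambda = lambda))
  }
  D <- ks_stat(counts, lambda)
  null_D <- vapply(seq_len(nsim), function(i) {
    x <- stats::rpois(length(counts), lambda)
    ks_stat(x, mean(x))
  }, 0)
  list(statistic = D, p_value = mean(null_D >= D - 1e-12),
       counts = counts, lambda = lambda)
}

#' Foldback-distance summaries
#'
#' The distance `d = pos_b - pos_a` between the two aligned ends of a
#' foldback junction measures how much sequence was lost (or separated) at
#' the fold; a long tail of distances indicates that fusion requires
#' proximity but not a palindromic sequence.
#'
#' @param foldbacks a [foldback_set].
#' @param cutoff_bp distance defining the reported tail fraction (default
#'   1000).
#' @return `list(distances, fraction_gt_cutoff, cdf)` where `cdf` is the
#'   empirical CDF function of the distances.
#' @export
foldback_distance_stats <- function(foldbacks, cutoff_bp = 1000) {
  if (nrow(foldbacks) == 0L) stop("empty foldback list")
  d <- foldbacks$pos_b - foldbacks$pos_a
  list(distances = d,
       fraction_gt_cutoff = mean(d > cutoff_bp),
       cdf = stats::ecdf(d))
}
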