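# Simulation benchmark: positives and negatives through the full pipeline,
# F1 over a threshold sweep, and grid-search parameter calibration.

# score one rendered case end to end; returns the minimum region score
# (sentinel when nothing passes the filters) plus breakdown components
score_case <- function(track, foldbacks, params, seed) {
  params$seed <- as.integer(seed)
  sel <- select_labels(track, foldbacks, params$cn_min, params$fb_excess,
                       params$fb_window_bp)
  regions <- link_and_cluster(sel, track, params$link_dist_bp, params$link_cn)
  empty <- list(score = params$sentinel, classification = "filtered",
                n = NA_integer_, copy_term = NA_real_, euclid = NA_real_,
                F = NA_integer_, delta_data = NA_real_)
  if (nrow(regions) == 0L) return(empty)
  fits <- lapply(seq_len(nrow(regions)), function(i) {
    bfb_fit(track, foldbacks,
            region = regions[i, c("chrom", "start", "end")],
            params = params, seed = seed + i)
  })
  scores <- vapply(fits, `[[`, 0, "score")
  fit <- fits[[which.min(scores)]]
  b <- fit$breakdown
  list(score = fit$score, classification = fit$classification,
       n = if (is.null(b)) NA_integer_ else b$n,
       copy_term = if (is.null(b)) NA_real_ else b$copy_term,
       euclid = if (is.null(b)) NA_real_ else b$euclid,
       F = if (is.null(b)) NA_integer_ else b$F,
       delta_data = if (is.null(b)) NA_real_ else b$delta_data)
}

#' Simulation benchmark of the full detection pipeline
#'
#' Simulates BFB positives (tiers cycled simple/intermediate/complex, target
#' segment counts uniform on `seg_range`, target mean copy numbers uniform
#' on `cn_range`) and negatives (ecDNA-like and chromothripsis-like
#' structures mixed `neg_mix:1`), renders each with the supplied rendering
#' configuration, scores every case with the full pipeline
#' (candidate-region selection, segmentation, enumeration, Gibbs
#' refinement), and sweeps score thresholds to locate the maximum F1.
#'
#' @param n_pos,n_neg numbers of positive and negative cases (>= 1).
#' @param params a [bfb_params].
#' @param render a [render_config]; its seed is re-derived per case.
#'   Boundary mode alternates sharp/gradual across cases when
#'   `mix_boundaries` is TRUE, mirroring the two segmentation-boundary
#'   regimes of real data.
#' @param seg_range,cn_range positive-case design ranges (segments 1-7,
#'   mean copy number 5-80 by default).
#' @param neg_mix ecDNA : chromothripsis ratio (default 5).
#' @param mix_boundaries alternate sharp and gradual rendering.
#' @param seed master seed; every case seed derives from it.
#' @return A list of class `bfb_benchmark`: `cases` (per-case scores,
#'   labels, stratifiers and score components), `f1_curve`
#'   (threshold/precision/recall/F1), `max_f1`, `best_threshold`, and
#'   `confusion` at `params$threshold`.
#' @export
run_benchmark <- function(n_pos = 100, n_neg = 100, params = bfb_params(),
                          render = render_config(), seg_range = c(1L, 7L),
                          cn_range = c(5, 80), neg_mix = 5,
                          mix_boundaries = TRUE, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  seed <- as.integer(seed)
  tiers <- c("simple", "intermediate", "complex")
  rows <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    set.seed(seed + 7L * i)
    segs <- sample(seq.int(seg_range[1L], seg_range[2L]), 1L)
    cn <- runif(1, cn_range[1L], cn_range[2L])
    tier <- tiers[(i - 1L) %% 3L + 1L]
    sim <- simulate_bfb(sim_config(tier = tier, n_segments = segs,
                                   target_cn = cn, seed = seed + 7L * i + 1L))
    rc <- render
    rc$seed <- seed + 7L * i + 2L
    if (mix_boundaries) rc$boundary_mode <- if (i %% 2L) "sharp" else "gradual"
    obs <- render_observed(sim, rc)
    sc <- score_case(obs$track, obs$foldbacks, params, seed + 7L * i + 3L)
    rows[[i]] <- data.frame(case = i, label = "positive", kind = tier,
                            n_segments = segs, mean_cn = cn,
                            score = sc$score, classification = sc$classification,
                            n = sc$n, copy_term = sc$copy_term,
                            euclid = sc$euclid, F = sc$F,
                            delta_data = sc$delta_data,
                            stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_neg)) {
    i <- n_pos + j
    set.seed(seed + 7L * i)
    kind <- if (j %% (neg_mix + 1L) == 0L) "chromothripsis" else "ecdna"
    sim <- simulate_negative(kind, seed = seed + 7L * i + 1L)
    rc <- render
    rc$seed <- seed + 7L * i + 2L
    if (mix_boundaries) rc$boundary_mode <- if (i %% 2L) "sharp" else "gradual"
    obs <- render_observed(sim, rc)
    sc <- score_case(obs$track, obs$foldbacks, params, seed + 7L * i + 3L)
    mean_cn <- max(sim$structure$segments$cn) - 1
    rows[[i]] <- data.frame(case = i, label = "negative", kind = kind,
                            n_segments = NA_integer_, mean_cn = mean_cn,
                            score = sc$score, classification = sc$classification,
                            n = sc$n, copy_term = sc$copy_term,
                            euclid = sc$euclid, F = sc$F,
                            delta_data = sc$delta_data,
                            stringsAsFactors = FALSE)
  }
  cases <- do.call(rbind, rows)
  curve <- f1_curve(cases$score, cases$label == "positive")
  best <- curve[which.max(curve$f1), ]
  conf <- confusion_at(cases$score, cases$label == "positive",
                       params$threshold)
  structure(list(cases = cases, f1_curve = curve, max_f1 = best$f1,
                 best_threshold = best$threshold, confusion = conf,
                 params = params, seed = seed),
            class = "bfb_benchmark")
}

# F1 over a grid of thresholds (call positive iff score < threshold)
f1_curve <- function(scores, truth) {
  cuts <- sort(unique(scores))
  thr <- unique(c(cuts[1] / 2, (cuts[-length(cuts)] + cuts[-1]) / 2,
                  max(cuts) + 0.01))
  stats <- vapply(thr, function(t) {
    pred <- scores < t
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    prec <- if (tp + fp) tp / (tp + fp) else 0
    rec <- if (tp + fn) tp / (tp + fn) else 0
    f1 <- if (prec + rec) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  data.frame(threshold = thr, precision = stats[1, ], recall = stats[2, ],
             f1 = stats[3, ])
}

confusion_at <- function(scores, truth, threshold) {
  pred <- scores < threshold
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' @export
print.bfb_benchmark <- function(x, ...) {
  cat("<bfb_benchmark> ", sum(x$cases$label == "positive"), " positives, ",
      sum(x$cases$label == "negative"), " negatives\n", sep = "")
  cat(sprintf("  max F1 = %.3f at threshold %.3f\n", x$max_f1,
              x$best_threshold))
  cat("  confusion at", x$params$threshold, ":",
      paste(names(x$confusion), x$confusion, collapse = ", "), "\n")
  invisible(x)
}

#' Grid-search calibration of the scoring parameters
#'
#' Re-weights stored per-case score components over a grid of `(p1, alpha,
#' c)` and returns the grid point whose best-threshold F1 is maximal, ties
#' broken by smallest `(p1, alpha, |c - 1|)`.  Cases removed by the filters
#' keep their sentinel score under every parameterisation.
#'
#' @param cases the `cases` data.frame of a [run_benchmark()] result (needs
#'   `copy_term`, `euclid`, `F`, `delta_data`, `n`, `score`, `label`).
#' @param p1_grid,alpha_grid,c_grid parameter grids.
#' @param sentinel score for filtered cases.
#' @return `list(p1, alpha, c, f1, threshold)`.
#' @export
calibrate_params <- function(cases, p1_grid = 0:10, alpha_grid = 3:10,
                             c_grid = seq(0.8, 1.2, by = 0.1),
                             sentinel = 4) {
  truth <- cases$label == "positive"
  if (!any(truth) || all(truth))
    stop("calibration needs at least one positive and one negative case")
  grid <- expand.grid(p1 = p1_grid, alpha = alpha_grid, c = c_grid)
  grid <- grid[order(grid$p1, grid$alpha, abs(grid$c - 1)), ]
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    p <- grid[g, ]
    dm <- cases$copy_term + p$alpha * cases$euclid + p$p1 * cases$F
    sc <- (dm + cases$delta_data) / cases$n^p$c
    sc[is.na(sc)] <- sentinel
    curve <- f1_curve(sc, truth)
    k <- which.max(curve$f1)
    if (is.null(best) || curve$f1[k] > best$f1 + 1e-12) {
      best <- list(p1 = p$p1, alpha = p$alpha, c = p$c, f1 = curve$f1[k],
                   threshold = curve$threshold[k])
    }
  }
  best
}
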