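#' Detection and scoring parameters
#'
#' All tunable thresholds of the pipeline live here, each with its published
#' default.  The score of a candidate architecture is
#' \deqn{\mathrm{score} = \frac{\Delta_{model} + \Delta_{data}}{n^{c}}}
#' where \eqn{\Delta_{model}} compares the latent segment profile
#' \eqn{(C^o, L^o, R^o)} with the candidate's \eqn{(C, L, R)} (copy term,
#' `alpha`-weighted Euclidean foldback term, and `p1` per missing-foldback
#' segment), and \eqn{\Delta_{data}} is the summed per-segment mean absolute
#' deviation of label copy numbers from \eqn{C^o}.
#'
#' @param alpha weight of the Euclidean foldback term (default 7).
#' @param p1 penalty per segment whose predicted foldback is absent while an
#'   observed one is present (default 1).
#' @param c exponent of the segment-count normalisation (default 0.9).
#' @param threshold score below which an amplicon is called BFB-positive
#'   (default 1.8).
#' @param sentinel score reported for amplicons removed by the candidate
#'   filters (default 4); never compared against `threshold`.
#' @param cn_min copy-number filter for candidate labels, strict (default 3).
#' @param fb_excess multiplicative foldback-enrichment factor over the
#'   genome-wide per-label mean (default 1.1, i.e. "over 10% more").
#' @param link_dist_bp maximum distance for linking consecutive selected
#'   labels (default 1.5e6).
#' @param link_cn mean copy number above which consecutive selected labels are
#'   linked regardless of distance (default 7).
#' @param fb_window_bp window for assigning a foldback junction to its nearest
#'   label (default 5e4).
#' @param weight_cap_bp inter-label gap at which the CBS weight saturates at 1
#'   (default 1e4).
#' @param smooth_frac genomic-length fraction below which a monotone middle
#'   segment is merged during post-hoc smoothing (default 0.07).
#' @param cbs_alpha,cbs_nperm permutation significance level and count for the
#'   weighted CBS split test.
#' @param gibbs_iters Gibbs refinement iterations (default 1200, with
#'   early exit at score zero or a 400-iteration plateau).
#' @param max_candidates,max_cycles,node_budget architecture-enumeration
#'   bounds (candidates kept, growth-cycle depth, search-node budget).
#' @param pad_bp flanking context added around a candidate region before
#'   fitting, so the architecture can use the centromeric flank and the
#'   telomeric-loss signal (default 3e5).
#' @param orientation `"auto"` fits both arm orientations and keeps the lower
#'   score; `"fwd"`/`"rev"` force centromere-at-left / centromere-at-right.
#' @param seed integer seed controlling every stochastic step.
#' @return A named list of class `bfb_params`.
#' @examples
#' p <- bfb_params(alpha = 7, c = 0.9)
#' p$threshold
#' @export
bfb_params <- function(alpha = 7, p1 = 1, c = 0.9, threshold = 1.8,
                       sentinel = 4, cn_min = 3, fb_excess = 1.1,
                       link_dist_bp = 1.5e6, link_cn = 7, fb_window_bp = 5e4,
                       weight_cap_bp = 1e4, smooth_frac = 0.07,
                       cbs_alpha = 0.01, cbs_nperm = 200,
                       gibbs_iters = 1200, max_candidates = 24,
                       max_cycles = 14, node_budget = 60000,
                       pad_bp = 3e5, orientation = "auto", seed = 1L) {
  stopifnot(alpha >= 0, p1 >= 0, c > 0, threshold > 0, threshold < sentinel,
            orientation %in% c("auto", "fwd", "rev"))
  structure(list(alpha = alpha, p1 = p1, c = c, threshold = threshold,
                 sentinel = sentinel, cn_min = cn_min, fb_excess = fb_excess,
                 link_dist_bp = link_dist_bp, link_cn = link_cn,
                 fb_window_bp = fb_window_bp, weight_cap_bp = weight_cap_bp,
                 smooth_frac = smooth_frac, cbs_alpha = cbs_alpha,
                 cbs_nperm = cbs_nperm, gibbs_iters = gibbs_iters,
                 max_candidates = max_candidates, max_cycles = max_cycles,
                 node_budget = node_budget, pad_bp = pad_bp,
                 orientation = orientation, seed = as.integer(seed)),
            class = "bfb_params")
}

#' @export
print.bfb_params <- function(x, ...) {
  cat("<bfb_params>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "bfb_params")) return(params)
  if (is.null(params)) return(bfb_params())
  do.call(bfb_params, params)
}
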