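# The discrepancy score: model fit (latent vs candidate architecture) plus
# data fit (labels vs latent), normalised by segment count.

#' Expected molecules per unit copy number
#'
#' `Z1` is the expected number of raw molecules covering a label present at
#' copy number 1, estimated as `sum(V) / sum(N)` over all labels of the
#' track.  It converts molecule counts (foldback support) into copy-number
#' units.
#'
#' @param track a [label_track].
#' @return A positive scalar.
#' @examples
#' estimate_z1(label_track("chr1", c(0, 5000, 10000), c(20, 20, 40), c(2, 2, 4)))
#' @export
estimate_z1 <- function(track) {
  sN <- sum(track$cn)
  if (!isTRUE(sN > 0)) stop("all-zero copy numbers: Z1 is undefined")
  sum(track$coverage) / sN
}

#' Observed foldback copy number of a segment
#'
#' The observed left/right foldback copy numbers of a segment are the sizes
#' of the unions of supporting molecule sets over the segment's labels,
#' divided by `z1`.  The union (not the sum) deduplicates molecules seen at
#' several labels.
#'
#' @param foldbacks a [foldback_set] restricted to the records assigned to
#'   the segment.
#' @param z1 molecules per copy, from [estimate_z1()].
#' @return `c(L = , R = )`, the observed foldback copy numbers.
#' @export
observed_foldback_cn <- function(foldbacks, z1) {
  stopifnot(z1 > 0)
  cnt <- function(side) {
    rows <- which(foldbacks$side == side)
    length(unique(unlist(foldbacks$molecules[rows]))) / z1
  }
  c(L = cnt("left"), R = cnt("right"))
}

#' Model discrepancy between a latent profile and a candidate architecture
#'
#' The copy term sums `|C_o[i] - C[i]| / max(C[i], 1)`; the foldback term is
#' `alpha` times the Euclidean distance between the concatenated observed and
#' candidate foldback vectors; `F` counts segments where a foldback is
#' observed but the candidate predicts none (a predicted-but-unobserved
#' foldback is not penalised beyond the Euclidean term, since foldbacks are
#' easily missed in real data), each costing `p1`.
#'
#' @param latent list with numeric vectors `C_o`, `L_o`, `R_o` (equal
#'   length).
#' @param cand candidate with integer vectors `C`, `L`, `R` of the same
#'   length (e.g. one element of [enumerate_architectures()]).
#' @param params a [bfb_params] (uses `alpha`, `p1`).
#' @return `list(value = , F = )`.
#' @export
delta_model <- function(latent, cand, params = bfb_params()) {
  n <- length(cand$C)
  if (length(latent$C_o) != n)
    stop("latent profile and candidate have different segment counts")
  copy_term <- sum(abs(latent$C_o - cand$C) / pmax(cand$C, 1))
  eu <- sqrt(sum((c(latent$L_o, latent$R_o) - c(cand$L, cand$R))^2))
  F_cnt <- sum((cand$R == 0 & latent$R_o != 0) | (cand$L == 0 & latent$L_o != 0))
  list(value = copy_term + params$alpha * eu + params$p1 * F_cnt, F = F_cnt)
}

#' Data discrepancy between labels and a latent profile
#'
#' Sum over segments of the mean absolute deviation of the member labels'
#' copy numbers from the segment's latent copy number `C_o`.
#'
#' @param N per-label copy numbers.
#' @param seg_of integer segment assignment (1..n) per label; every segment
#'   must be non-empty.
#' @param C_o latent per-segment copy numbers.
#' @return A non-negative scalar.
#' @export
delta_data <- function(N, seg_of, C_o) {
  n <- length(C_o)
  tab <- tabulate(seg_of, nbins = n)
  if (any(tab == 0L)) stop("every segment must contain at least one label")
  sum(vapply(seq_len(n), function(s) {
    mean(abs(N[seg_of == s] - C_o[s]))
  }, 0))
}

#' The BFB score
#'
#' `(delta_model + delta_data) / n^c`: low scores mean the observed copy
#' numbers and foldbacks are well explained by a sequence of BFB cycles.
#'
#' @param delta_model_value,delta_data_value the two discrepancies.
#' @param n number of segments.
#' @param params a [bfb_params] (uses `c`).
#' @return The score.
#' @examples
#' bfb_score(0.5, 0.5, 2)  # 1 / 2^0.9
#' @export
bfb_score <- function(delta_model_value, delta_data_value, n,
                      params = bfb_params()) {
  stopifnot(n >= 1)
  (delta_model_value + delta_data_value) / n^params$c
}

# weighted median: robust segment copy value (boundary-ramp labels are a
# minority and must not pull the segment value off its plateau)
wmedian <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1L]]
}

# Build the initial latent profile for a region track from a (smoothed)
# segmentation: C_o are weighted median label copy numbers, L_o/R_o come
# from the foldback records assigned to each segment's labels (union of
# molecules, divided by z1).  The data-derived values are kept alongside
# (C_d, L_d, R_d) as the anchors for resampling proposals.  `fb_map` is the
# assign_foldbacks() mapping computed on the region track.
init_latent <- function(region_track, seg, foldbacks, fb_map, z1,
                        weights = NULL) {
  n <- nrow(seg)
  if (is.null(weights)) weights <- attr(seg, "weights")
  if (is.null(weights)) weights <- rep(1, nrow(region_track))
  C_o <- numeric(n)
  L_o <- numeric(n); R_o <- numeric(n)
  for (s in seq_len(n)) {
    labs <- seg$start_label[s]:seg$end_label[s]
    C_o[s] <- wmedian(region_track$cn[labs], weights[labs])
    recs <- unique(fb_map$record[fb_map$label %in% labs])
    if (length(recs)) {
      ob <- observed_foldback_cn(foldbacks[recs, , drop = FALSE], z1)
      L_o[s] <- ob[["L"]]; R_o[s] <- ob[["R"]]
    }
  }
  boundaries <- c(seg$start_label, seg$end_label[n] + 1L)
  list(boundaries = boundaries, C_o = C_o, L_o = L_o, R_o = R_o,
       C_d = C_o, L_d = L_o, R_d = R_o)
}

# segment assignment vector (1..n per label) from latent boundaries
seg_assign <- function(latent, m) {
  findInterval(seq_len(m), latent$boundaries[-length(latent$boundaries)])
}
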