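#' Label weights for weighted segmentation
#'
#' Optical-map labels are not uniformly spaced, so each label is weighted by
#' the inter-label gap preceding it: gaps of at least `cap_bp` (10 kbp by
#' default) get weight 1, shorter gaps get `gap / cap_bp`.  The first label
#' has no preceding gap and uses its following gap.
#'
#' @param positions strictly increasing label positions (bp).
#' @param cap_bp saturation gap in bp (default 10000).
#' @return Numeric weights in `(0, 1]`, one per label.
#' @examples
#' label_weights(c(0, 20000, 25000))  # gaps 20000, 5000 -> 1.0, 1.0, 0.5
#' @export
label_weights <- function(positions, cap_bp = 1e4) {
  m <- length(positions)
  if (m < 2L) stop("at least 2 labels are required to define weights")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  gaps <- c(positions[2L] - positions[1L], diff(positions))
  pmin(1, gaps / cap_bp)
}

#' Weighted circular binary segmentation of a label track
#'
#' Partitions the per-label copy-number signal `N` into segments of constant
#' mean using circular binary segmentation with label weights: each label's
#' contribution to segment means and to the split statistic is multiplied by
#' its weight.  Splits are accepted when a permutation test on the maximal
#' weighted arc statistic is significant.
#'
#' @param track a label track (see [label_track()]) restricted to one
#'   chromosome, or any data.frame with columns `pos` and `cn`.
#' @param weights per-label weights; defaults to [label_weights()] on the
#'   track positions (uniform for a single label).
#' @param alpha permutation significance level for accepting a split.
#' @param nperm number of permutations.
#' @param min_width minimum labels per segment.
#' @param seed seed for the permutation stream.
#' @return A data.frame of class `cbs_segmentation` with columns
#'   `start_label`, `end_label` (1-based, inclusive label index ranges),
#'   `mean` (weighted mean copy number), and attributes `breakpoints` (label
#'   indices beginning each segment after the first) and `weights`.
#' @examples
#' tr <- data.frame(pos = seq(0, 99) * 5000, cn = rep(c(2, 10), each = 50))
#' cbs_segment(tr)
#' @export
cbs_segment <- function(track, weights = NULL, alpha = 0.01, nperm = 300,
                        min_width = 2, seed = 1L) {
  x <- as.numeric(track$cn)
  pos <- as.numeric(track$pos)
  m <- length(x)
  if (m == 0L) stop("empty track")
  if (is.null(weights))
    weights <- if (m >= 2L) label_weights(pos) else 1
  stopifnot(length(weights) == m, all(weights > 0))
  segs <- list()
  recurse <- function(lo, hi, depth) {            # 1-based inclusive
    mlen <- hi - lo + 1L
    if (mlen < 2L * min_width || depth > 40L) {
      segs[[length(segs) + 1L]] <<- c(lo, hi)
      return(invisible())
    }
    sc <- .cbs_scan_cpp(x[lo:hi], weights[lo:hi], as.integer(min_width),
                        as.integer(nperm), alpha,
                        as.integer(seed + lo * 7L + hi))
    if (!isTRUE(sc$significant)) {
      segs[[length(segs) + 1L]] <<- c(lo, hi)
      return(invisible())
    }
    i <- sc$i; j <- sc$j                          # arc (i, j], 0-based offsets
    cuts <- unique(c(lo + i, lo + j))             # first labels of new segments
    cuts <- cuts[cuts > lo & cuts <= hi]
    bounds <- c(lo, cuts, hi + 1L)
    for (k in seq_len(length(bounds) - 1L))
      recurse(bounds[k], bounds[k + 1L] - 1L, depth + 1L)
  }
  recurse(1L, m, 0L)
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  means <- apply(segs, 1L, function(se) {
    idx <- se[1L]:se[2L]
    sum(weights[idx] * x[idx]) / sum(weights[idx])
  })
  out <- data.frame(start_label = segs[, 1L], end_label = segs[, 2L],
                    mean = means)
  class(out) <- c("cbs_segmentation", "data.frame")
  attr(out, "breakpoints") <- out$start_label[-1L]
  attr(out, "weights") <- weights
  out
}

#' Post-hoc smoothing of a segmentation
#'
#' Very short segments produced at sharp copy-number transitions are merged
#' away: while some middle segment of a strictly monotone triplet spans less
#' than `frac` (7% by default) of the total region length, it is merged into
#' the neighbouring segment closest in copy number, and the merged mean is
#' recomputed as the label-weighted average.  The operation never increases
#' the segment count and is idempotent.
#'
#' @param seg a [cbs_segment()] result.
#' @param track the label track the segmentation was computed on (supplies
#'   positions for genomic lengths and the copy-number values for merged
#'   means).
#' @param region_length_bp total region length; defaults to the track span.
#' @param frac length fraction defining "short" (default 0.07).
#' @return A `cbs_segmentation` with the same structure.
#' @export
smooth_segments <- function(seg, track, region_length_bp = NULL, frac = 0.07) {
  pos <- as.numeric(track$pos)
  x <- as.numeric(track$cn)
  w <- attr(seg, "weights")
  if (is.null(w)) w <- if (length(pos) >= 2L) label_weights(pos) else 1
  if (is.null(region_length_bp))
    region_length_bp <- max(pos) - min(pos) + 1
  s <- as.data.frame(seg)
  seg_len <- function(k) {
    # genomic span of segment k: to the start of the next segment's first label
    from <- pos[s$start_label[k]]
    to <- if (k < nrow(s)) pos[s$start_label[k + 1L]] else max(pos) + 1
    to - from
  }
  repeat {
    ns <- nrow(s)
    if (ns < 3L) break
    merged <- FALSE
    for (k in 2L:(ns - 1L)) {
      tri <- s$mean[(k - 1L):(k + 1L)]
      mono <- all(diff(tri) > 0) || all(diff(tri) < 0)
      if (!mono || seg_len(k) >= frac * region_length_bp) next
      into <- if (abs(tri[2L] - tri[1L]) <= abs(tri[2L] - tri[3L])) k - 1L else k + 1L
      a <- min(k, into); b <- max(k, into)
      idx <- s$start_label[a]:s$end_label[b]
      s$end_label[a] <- s$end_label[b]
      s$mean[a] <- sum(w[idx] * x[idx]) / sum(w[idx])
      s <- s[-b, , drop = FALSE]
      rownames(s) <- NULL
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  class(s) <- c("cbs_segmentation", "data.frame")
  attr(s, "breakpoints") <- s$start_label[-1L]
  attr(s, "weights") <- w
  s
}


# Greedy split refinement: while some segment admits a two-means cut that
# lowers its mean absolute deviation by at least `min_gain`, apply the best
# such cut.  Catches short runs that the permutation test left unsplit;
# spurious extra splits are harmless downstream (merge moves and the
# distinct-run normalisation absorb them).
refine_segments <- function(seg, track, weights = NULL, min_gain = 0.3,
                            max_extra = 12L) {
  x <- as.numeric(track$cn)
  w <- if (is.null(weights)) attr(seg, "weights") else weights
  if (is.null(w)) w <- rep(1, length(x))
  s <- as.data.frame(seg)
  for (round in seq_len(max_extra)) {
    best <- NULL
    for (k in seq_len(nrow(s))) {
      lo <- s$start_label[k]; hi <- s$end_label[k]
      if (hi - lo < 1L) next
      xs <- x[lo:hi]; ws <- w[lo:hi]
      mu <- sum(ws * xs) / sum(ws)
      mad0 <- mean(abs(xs - mu))
      cw <- cumsum(ws); cx <- cumsum(ws * xs)
      kk <- seq_len(length(xs) - 1L)
      m1 <- cx[kk] / cw[kk]
      m2 <- (cx[length(xs)] - cx[kk]) / (cw[length(xs)] - cw[kk])
      gains <- vapply(kk, function(j) {
        mad0 - mean(abs(c(xs[1:j] - m1[j], xs[(j + 1):length(xs)] - m2[j])))
      }, 0)
      # reject boundary-ramp artifacts: a NARROW piece whose mean
      # interpolates between its outer neighbour and the other piece is a
      # blurred transition, not a copy-number segment (wide monotone pieces
      # are genuine -- BFB ladders are monotone staircases)
      npix <- length(xs)
      is_ramp <- function(j) {
        left_nb <- if (k > 1L) s$mean[k - 1L] else NA_real_
        right_nb <- if (k < nrow(s)) s$mean[k + 1L] else NA_real_
        (j <= 7L && !is.na(left_nb) &&
           (m1[j] - left_nb) * (m2[j] - m1[j]) > 0) ||
        (npix - j <= 7L && !is.na(right_nb) &&
           (m2[j] - right_nb) * (m1[j] - m2[j]) > 0)
      }
      ok <- which(gains >= min_gain)
      ok <- ok[!vapply(ok, is_ramp, TRUE)]
      if (length(ok)) {
        j <- ok[which.max(gains[ok])]
        if (is.null(best) || gains[j] > best$gain)
          best <- list(k = k, cut = lo + j, gain = gains[j])
      }
    }
    if (is.null(best)) break
    k <- best$k
    top <- s[seq_len(k - 1L), , drop = FALSE]
    bot <- s[seq(k + 1L, length.out = nrow(s) - k), , drop = FALSE]
    lo <- s$start_label[k]; hi <- s$end_label[k]
    mk <- function(a, b) {
      idx <- a:b
      data.frame(start_label = a, end_label = b,
                 mean = sum(w[idx] * x[idx]) / sum(w[idx]))
    }
    s <- rbind(top, mk(lo, best$cut - 1L), mk(best$cut, hi), bot)
    rownames(s) <- NULL
  }
  class(s) <- c("cbs_segmentation", "data.frame")
  attr(s, "breakpoints") <- s$start_label[-1L]
  attr(s, "weights") <- w
  s
}
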