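# Fitting a BFB architecture to one candidate region, and the bfb_fit class.

# Mirror a region track (and its foldbacks) so that index 1 becomes the
# telomere-proximal end; left and right foldbacks swap roles.
orient_region <- function(track, foldbacks, reverse = FALSE) {
  if (!reverse)
    return(list(track = track, foldbacks = foldbacks,
                orig_idx = seq_len(nrow(track)), reverse = FALSE))
  M <- max(track$pos) + min(track$pos)
  tr <- track
  tr$pos <- M - track$pos
  ord <- order(tr$pos)
  tr <- tr[ord, , drop = FALSE]
  rownames(tr) <- NULL
  fb <- foldbacks
  if (nrow(fb)) {
    pa <- M - fb$pos_b
    pb <- M - fb$pos_a
    fb$pos_a <- pa; fb$pos_b <- pb
    fb$side <- ifelse(fb$side == "left", "right", "left")
  }
  list(track = tr, foldbacks = fb, orig_idx = rev(seq_len(nrow(track)))[order(tr$pos)],
       reverse = TRUE)
}

# restrict track/foldbacks to a padded window around the region
region_slice <- function(track, foldbacks, region, pad_bp, fb_window_bp) {
  lo <- region$start - pad_bp
  hi <- region$end + pad_bp
  ti <- which(track$chrom == region$chrom & track$pos >= lo & track$pos < hi)
  tr <- track[ti, , drop = FALSE]
  rownames(tr) <- NULL
  fi <- which(foldbacks$chrom == region$chrom &
                foldbacks$pos_a >= lo - fb_window_bp &
                foldbacks$pos_b < hi + fb_window_bp)
  fb <- foldbacks[fi, , drop = FALSE]
  rownames(fb) <- NULL
  list(track = tr, foldbacks = fb)
}

#' Fit a BFB architecture to a candidate region
#'
#' `bfb_fit()` is the central fitting function: given label-level evidence
#' and a genomic region, it segments the copy-number signal, enumerates
#' candidate BFB architectures, refines the latent segment profile by Gibbs
#' sampling, and classifies the amplicon.  `classify_amplicon()` is an alias
#' with the region argument first.
#'
#' Classification outcomes:
#' \describe{
#'   \item{`filtered`}{the region fails the candidate filters (no amplified
#'     label with a foldback excess); the sentinel score is reported and
#'     never compared to the threshold.}
#'   \item{`filtered_ecDNA_like`}{the fitted structure is a single amplified
#'     segment carrying both left and right foldbacks with intact flanks --
#'     the signature of an ecDNA duplication-inversion, indistinguishable
#'     from a one-segment BFB ladder except through the telomeric-loss
#'     signal, which is absent here.}
#'   \item{`BFB_positive` / `BFB_negative`}{fitted score below / at-or-above
#'     `params$threshold`.}
#' }
#'
#' @param track a [label_track] (whole-genome or arm-scale; used both for
#'   the region evidence and for genome-wide normalisations such as the
#'   foldback-excess mean and `Z1`).
#' @param foldbacks a [foldback_set].
#' @param region `list(chrom =, start =, end =)` (0-based half-open); when
#'   `NULL`, the candidate region containing the most selected labels is
#'   used.
#' @param params a [bfb_params].
#' @param seed seed for the stochastic refinement; defaults to
#'   `params$seed`.
#' @return An object of class `bfb_fit`; see Details.  Key fields:
#'   `classification`, `score`, `string`, `C`, `L`, `R`, `segments` (fitted
#'   genomic segments in centromere-to-telomere order), `breakdown`,
#'   `orientation`.
#' @seealso [detect()] for the genome-wide screen, [enumerate_architectures()]
#'   for the combinatorial layer.
#' @export
bfb_fit <- function(track, foldbacks, region = NULL, params = bfb_params(),
                    seed = params$seed) {
  params$seed <- as.integer(seed)
  set.seed(params$seed)
  sel <- select_labels(track, foldbacks, params$cn_min, params$fb_excess,
                       params$fb_window_bp)
  if (is.null(region)) {
    regions <- link_and_cluster(sel, track, params$link_dist_bp, params$link_cn)
    if (nrow(regions) == 0L)
      stop("no candidate region passes the filters; supply `region` to force one")
    pick <- which.max(vapply(regions$labels, length, 0L))
    region <- regions[pick, c("chrom", "start", "end")]
  }
  region <- as.list(region)[c("chrom", "start", "end")]

  in_region <- sel[track$chrom[sel] == region$chrom &
                     track$pos[sel] >= region$start &
                     track$pos[sel] < region$end]
  if (!length(in_region))
    return(new_bfb_fit(region, "filtered", params$sentinel, params,
                       reason = "no selected label in region"))

  sl <- region_slice(track, foldbacks, region, params$pad_bp,
                     params$fb_window_bp)
  rt <- sl$track; rfb <- sl$foldbacks
  if (nrow(rt) < 2L)
    return(new_bfb_fit(region, "filtered", params$sentinel, params,
                       reason = "too few labels"))
  z1 <- estimate_z1(track)

  # forward-orientation segmentation drives the ecDNA-like filter and the
  # orientation heuristic
  w <- label_weights(rt$pos, params$weight_cap_bp)
  seg <- cbs_segment(rt, weights = w, alpha = params$cbs_alpha,
                     nperm = params$cbs_nperm, seed = params$seed)
  seg <- smooth_segments(seg, rt, region_length_bp = region$end - region$start,
                         frac = params$smooth_frac)
  seg <- refine_segments(seg, rt, weights = w)
  fb_map <- assign_foldbacks(rt, rfb, params$fb_window_bp)
  latent_f <- init_latent(rt, seg, rfb, fb_map, z1)

  amp <- which(seg$mean > params$cn_min)
  if (length(amp) == 1L) {
    i <- amp
    both <- latent_f$L_o[i] > 0 && latent_f$R_o[i] > 0
    nb <- c(if (i > 1L) seg$mean[i - 1L], if (i < nrow(seg)) seg$mean[i + 1L])
    loss <- any(nb < 0.5)
    if (both && !loss)
      return(new_bfb_fit(region, "filtered_ecDNA_like", params$sentinel,
                         params, reason = "single amplified segment with left and right foldbacks"))
  }

  orientations <- switch(params$orientation,
                         fwd = FALSE, rev = TRUE,
                         auto = {
                           lo_first <- seg$mean[1L] < 0.5
                           lo_last <- seg$mean[nrow(seg)] < 0.5
                           if (lo_last && !lo_first) FALSE
                           else if (lo_first && !lo_last) TRUE
                           else c(FALSE, TRUE)
                         })
  fits <- lapply(orientations, function(rev) {
    ot <- orient_region(rt, rfb, reverse = rev)
    lat <- if (!rev) latent_f else NULL
    res <- gibbs_refine(ot$track, ot$foldbacks, candidates = NULL,
                        params = params, latent = lat,
                        region_length_bp = region$end - region$start)
    list(res = res, orient = ot)
  })
  scores <- vapply(fits, function(f) f$res$breakdown$score, 0)
  pick <- which.min(scores)
  fit <- fits[[pick]]
  res <- fit$res
  cls <- if (res$breakdown$score < params$threshold) "BFB_positive" else "BFB_negative"

  out <- new_bfb_fit(region, cls, res$breakdown$score, params)
  out$breakdown <- res$breakdown
  out$latent <- res$latent
  out$candidate <- res$candidate
  out$string <- res$breakdown$string
  if (!is.null(res$candidate)) {
    out$C <- res$candidate$C; out$L <- res$candidate$L; out$R <- res$candidate$R
  }
  out$orientation <- if (fit$orient$reverse) "rev" else "fwd"
  out$z1 <- z1
  out$track <- fit$orient$track
  out$foldbacks <- fit$orient$foldbacks
  out$segments <- latent_segments(region$chrom, fit$orient$track, res$latent)
  out
}

# genomic intervals of the fitted segments, in architecture order
latent_segments <- function(chrom, track, latent) {
  b <- latent$boundaries
  n <- length(latent$C_o)
  data.frame(chrom = chrom,
             start = track$pos[b[-length(b)]],
             end = c(track$pos[b[-c(1L, length(b))] - 1L] + 1,
                     max(track$pos) + 1),
             C_o = latent$C_o, L_o = latent$L_o, R_o = latent$R_o,
             stringsAsFactors = FALSE)
}

new_bfb_fit <- function(region, classification, score, params, reason = NULL) {
  structure(list(region = region, classification = classification,
                 score = score, string = NA_character_,
                 C = NULL, L = NULL, R = NULL, segments = NULL,
                 breakdown = NULL, latent = NULL, candidate = NULL,
                 orientation = NA_character_, z1 = NA_real_,
                 reason = reason, params = params, seed = params$seed),
            class = "bfb_fit")
}

#' @rdname bfb_fit
#' @export
classify_amplicon <- function(region, track, foldbacks, params = bfb_params(),
                              seed = params$seed) {
  bfb_fit(track, foldbacks, region = region, params = params, seed = seed)
}

#' @export
print.bfb_fit <- function(x, ...) {
  cat("<bfb_fit> ", x$region$chrom, ":",
      format(x$region$start, scientific = FALSE), "-",
      format(x$region$end, scientific = FALSE), "\n", sep = "")
  cat("  classification: ", x$classification,
      "   score: ", format(round(x$score, 4)), "\n", sep = "")
  if (!is.na(x$string)) cat("  architecture:  ", x$string, "\n", sep = " ")
  invisible(x)
}

#' @export
summary.bfb_fit <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$breakdown)) {
    b <- x$breakdown
    cat(sprintf("  n = %d segments; delta_model = %.4f (F = %s); delta_data = %.4f; Z1 = %.2f\n",
                b$n, b$delta_model, format(b$F), b$delta_data, b$z1))
  }
  if (!is.null(x$segments)) {
    cat("  fitted segments (centromere -> telomere):\n")
    print(x$segments, row.names = FALSE)
  }
  if (!is.null(x$reason)) cat("  filter reason:", x$reason, "\n")
  invisible(x)
}

#' @export
coef.bfb_fit <- function(object, ...) {
  if (is.null(object$C)) return(NULL)
  rbind(C = object$C, L = object$L, R = object$R)
}

#' @export
residuals.bfb_fit <- function(object, ...) {
  if (is.null(object$latent) || is.null(object$track)) return(numeric())
  sa <- seg_assign(object$latent, nrow(object$track))
  object$track$cn - object$latent$C_o[sa]
}
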