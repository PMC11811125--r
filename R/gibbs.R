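# Metropolis-within-Gibbs refinement of the latent segment profile.
#
# The latent state is a segmentation of the region's labels together with
# per-segment observed copy and foldback numbers (C_o, L_o, R_o).  The
# target is proportional to exp(-delta_model - delta_data), where
# delta_model is evaluated against the best-fitting enumerated candidate
# architecture for the current segment count.  Moves: resample one segment's
# (C_o, L_o, R_o) near its current values (probability 0.6), merge two
# adjacent segments (0.2), or split a segment at a label boundary (0.2).
# Dimension moves use data-driven deterministic proposal values and plain
# Metropolis acceptance on the target (no reversible-jump correction); the
# procedure is used as a stochastic minimiser and the minimum-score state
# visited is returned, so the final score never exceeds the initial one.

# best delta_model over a candidate list; returns index, value, F
best_model_fit <- function(latent, candidates, params) {
  if (length(candidates) == 0L)
    return(list(idx = NA_integer_, value = 10 * params$sentinel,
                F = NA_integer_))
  best <- NULL
  for (k in seq_along(candidates)) {
    dm <- delta_model(latent, candidates[[k]], params)
    if (is.null(best) || dm$value < best$value)
      best <- list(idx = k, value = dm$value, F = dm$F)
  }
  best
}

# enumeration with a per-call cache (environment), keyed by the rounded
# latent copy and foldback vectors
cached_enumeration <- function(cache, C_o, L_o, R_o, params, budget,
                               approx = TRUE) {
  key <- paste(c(pmax(0L, as.integer(round(C_o))),
                 as.integer(round(L_o)), as.integer(round(R_o))),
               collapse = ",")
  if (!is.null(cache[[key]])) return(cache[[key]])
  Cr <- pmax(0L, as.integer(round(C_o)))
  res <- if (all(Cr <= 0L) || Cr[1L] < 1L) {
    structure(list(), truncated = FALSE, exact = FALSE)
  } else {
    enumerate_architectures(Cr, max_candidates = params$max_candidates,
                            max_cycles = params$max_cycles,
                            L_obs = L_o, R_obs = R_o,
                            node_budget = budget, approx = approx)
  }
  cache[[key]] <- res
  res
}

# Transform a candidate list across a segmentation change, for cheap
# proposal evaluation: splitting reference segment i duplicates its copy
# number (each copy of the segment spans both halves) and puts the left
# foldbacks on the left half and the right foldbacks on the right half;
# merging two segments sums the foldbacks and averages the copy numbers
# (exact when they are equal, else an approximation refreshed by a real
# enumeration once the move is accepted).
split_candidates <- function(cands, i) {
  lapply(cands, function(x) {
    ins <- function(v, vals) append(v[-i], vals, after = i - 1L)
    list(string = x$string,
         C = ins(x$C, c(x$C[i], x$C[i])),
         L = ins(x$L, c(x$L[i], 0L)),
         R = ins(x$R, c(0L, x$R[i])),
         copy_discrepancy = x$copy_discrepancy)
  })
}

merge_candidates_at <- function(cands, j) {
  lapply(cands, function(x) {
    drop2 <- function(v, vals) append(v[-c(j, j + 1L)], vals, after = j - 1L)
    list(string = x$string,
         C = drop2(x$C, as.integer(round((x$C[j] + x$C[j + 1L]) / 2))),
         L = drop2(x$L, x$L[j] + x$L[j + 1L]),
         R = drop2(x$R, x$R[j] + x$R[j + 1L]),
         copy_discrepancy = x$copy_discrepancy)
  })
}

enumerate_full <- function(latent, params) {
  Cr <- pmax(0L, as.integer(round(latent$C_o)))
  if (all(Cr <= 0L) || Cr[1L] < 1L) return(list())
  enumerate_architectures(Cr, max_candidates = params$max_candidates,
                          max_cycles = params$max_cycles,
                          L_obs = latent$L_o, R_obs = latent$R_o,
                          node_budget = params$node_budget)
}

# weighted mean / foldback observation helpers over a label index range
range_cn <- function(track, w, labs) wmedian(track$cn[labs], w[labs])
range_fb <- function(foldbacks, fb_map, labs, z1) {
  recs <- unique(fb_map$record[fb_map$label %in% labs])
  if (!length(recs)) return(c(L = 0, R = 0))
  observed_foldback_cn(foldbacks[recs, , drop = FALSE], z1)
}

#' Gibbs refinement of the latent segment profile
#'
#' Starting from the deterministic segmentation-derived latent profile,
#' refines `(C_o, L_o, R_o)` and the segmentation itself by
#' Metropolis-within-Gibbs against the combined discrepancy, re-enumerating
#' candidate architectures whenever the segment count changes, and returns
#' the minimum-score configuration visited.
#'
#' @param track region label track, oriented centromere-first.
#' @param foldbacks [foldback_set] for the region (same orientation).
#' @param candidates optional pre-enumerated candidate list for the initial
#'   segment count; enumerated from the initial latent profile when `NULL`.
#' @param params a [bfb_params]; `gibbs_iters`, `alpha`, `p1`, `c` and the
#'   enumeration bounds are used.  The R random number stream drives the
#'   sampler, so results are reproducible under `set.seed()`.
#' @param latent optional initial latent profile (as built internally from
#'   [cbs_segment()] + [smooth_segments()]).
#' @param region_length_bp reference length for the smoothing rule (defaults
#'   to the track span).
#' @return `list(candidate, latent, breakdown)` where `breakdown` holds
#'   `delta_model`, `delta_data`, `F`, `z1`, `n`, `score`, and the candidate
#'   string; `candidate` is `NULL` when no architecture was admissible.
#' @export
gibbs_refine <- function(track, foldbacks, candidates = NULL,
                         params = bfb_params(), latent = NULL,
                         region_length_bp = NULL) {
  m <- nrow(track)
  w <- if (m >= 2L) label_weights(track$pos, params$weight_cap_bp) else 1
  z1 <- estimate_z1(track)
  fb_map <- assign_foldbacks(track, foldbacks, params$fb_window_bp)
  if (is.null(latent)) {
    seg <- cbs_segment(track, weights = w, alpha = params$cbs_alpha,
                       nperm = params$cbs_nperm, seed = params$seed)
    seg <- smooth_segments(seg, track, region_length_bp = region_length_bp,
                           frac = params$smooth_frac)
    seg <- refine_segments(seg, track, weights = w)
    latent <- init_latent(track, seg, foldbacks, fb_map, z1)
  }
  cache <- new.env(parent = emptyenv())
  budget <- min(params$node_budget, 4000L)
  if (is.null(candidates))
    candidates <- cached_enumeration(cache, latent$C_o, latent$L_o,
                                     latent$R_o, params, params$node_budget)

  eval_state <- function(latent, candidates) {
    n <- length(latent$C_o)
    # normalise by the number of distinct copy-number runs: splitting a
    # constant stretch must not inflate the score's segment count
    n_eff <- 1L + sum(abs(diff(latent$C_o)) > 0.5)
    bm <- best_model_fit(latent, candidates, params)
    dd <- delta_data(track$cn, seg_assign(latent, m), latent$C_o)
    sc <- if (is.na(bm$idx)) 10 * params$sentinel
          else bfb_score(bm$value, dd, n_eff, params)
    list(total = bm$value + dd, dm = bm$value, dd = dd, F = bm$F,
         idx = bm$idx, n = n, n_eff = n_eff, score = sc)
  }

  cur <- eval_state(latent, candidates)
  best <- list(latent = latent, candidates = candidates, ev = cur)
  grid_prop <- function(x, sd, grid) {
    abs(x + grid * round(rnorm(length(x), 0, sd) / grid))  # reflected at 0
  }
  iters <- params$gibbs_iters
  last_gain <- 0L
  for (it in seq_len(iters)) {
    if (best$ev$score <= 1e-9) break
    if (it - last_gain > 400L) break    # plateau: no improvement in 400 moves
    u <- runif(1)
    n <- length(latent$C_o)
    if (u >= 0.45 && u < 0.6 && n >= 2L) {
      # shift an internal boundary by up to three labels
      bi <- 1L + sample.int(n - 1L, 1L)
      delta <- sample(c(-3:-1, 1:3), 1L)
      prop <- shift_latent(latent, bi, delta, track, w, foldbacks, fb_map, z1)
      if (!is.null(prop)) {
        ev <- eval_state(prop, candidates)
        if (log(runif(1)) < cur$total - ev$total) {
          latent <- prop; cur <- ev
        }
      }
    } else if (u < 0.6 || n == 1L && u < 0.8) {
      i <- sample.int(n, 1L)
      prop <- latent
      # proposals are anchored at the data-derived values, so the latent
      # profile can flex by a copy or so but never walk away from the
      # observations (the data term does not constrain L_o and R_o)
      prop$C_o[i] <- grid_prop(latent$C_d[i], 1, 0.5)
      prop$L_o[i] <- grid_prop(latent$L_d[i], 0.5, 0.25)
      prop$R_o[i] <- grid_prop(latent$R_d[i], 0.5, 0.25)
      ev <- eval_state(prop, candidates)
      if (log(runif(1)) < cur$total - ev$total) {
        latent <- prop; cur <- ev
      }
    } else if (u < 0.8 && n >= 2L) {
      j <- sample.int(n - 1L, 1L)             # merge segments j, j+1
      prop <- merge_latent(latent, j, track, w, foldbacks, fb_map, z1)
      pc0 <- merge_candidates_at(candidates, j)
      ev <- eval_state(prop, pc0)
      if (log(runif(1)) < cur$total - ev$total) {
        pc <- merge_candidates(pc0,
                cached_enumeration(cache, prop$C_o, prop$L_o, prop$R_o,
                                   params, budget, approx = FALSE),
                params$max_candidates)
        ev2 <- eval_state(prop, pc)
        if (ev2$total > ev$total) { pc <- pc0; ev2 <- ev }
        latent <- prop; candidates <- pc; cur <- ev2
      }
    } else {
      sizes <- diff(latent$boundaries)
      ok <- which(sizes >= 2L)
      if (!length(ok)) next
      i <- ok[sample.int(length(ok), 1L)]
      lo <- latent$boundaries[i]; hi <- latent$boundaries[i + 1L] - 1L
      cut <- if (runif(1) < 0.5) {
        # best two-means cut of the segment's labels (weighted SSE)
        xs <- track$cn[lo:hi]; ws <- w[lo:hi]
        cw <- cumsum(ws); cx <- cumsum(ws * xs); cx2 <- cumsum(ws * xs^2)
        W <- cw[length(cw)]; X <- cx[length(cx)]; X2 <- cx2[length(cx2)]
        kk <- seq_len(length(xs) - 1L)
        sse <- (cx2[kk] - cx[kk]^2 / cw[kk]) +
          ((X2 - cx2[kk]) - (X - cx[kk])^2 / (W - cw[kk]))
        lo + which.min(sse)
      } else lo + sample.int(sizes[i] - 1L, 1L)
      prop <- split_latent(latent, i, cut, track, w, foldbacks, fb_map, z1)
      pc0 <- split_candidates(candidates, i)
      ev <- eval_state(prop, pc0)
      # a split that clearly improves the data fit is enumerated up front:
      # transformed candidates alone can veto cuts the true architecture
      # supports
      enumerate_first <- ev$dd < cur$dd - 0.5
      if (enumerate_first) {
        pc0 <- merge_candidates(pc0,
                 cached_enumeration(cache, prop$C_o, prop$L_o, prop$R_o,
                                    params, budget, approx = FALSE),
                 params$max_candidates)
        ev <- eval_state(prop, pc0)
      }
      if (log(runif(1)) < cur$total - ev$total) {
        pc <- if (enumerate_first) pc0 else merge_candidates(pc0,
                cached_enumeration(cache, prop$C_o, prop$L_o, prop$R_o,
                                   params, budget, approx = FALSE),
                params$max_candidates)
        ev2 <- eval_state(prop, pc)
        if (ev2$total > ev$total) { pc <- pc0; ev2 <- ev }
        latent <- prop; candidates <- pc; cur <- ev2
      }
    }
    if (cur$score < best$ev$score) {
      best <- list(latent = latent, candidates = candidates, ev = cur)
      last_gain <- it
    }
  }
  # final polish: the best latent found gets a full-budget enumeration (the
  # in-sampler searches are deliberately cheap)
  pol <- enumerate_full(best$latent, params)
  if (length(pol)) {
    pc <- merge_candidates(best$candidates, pol, params$max_candidates)
    ev2 <- eval_state(best$latent, pc)
    if (ev2$score <= best$ev$score)
      best <- list(latent = best$latent, candidates = pc, ev = ev2)
  }
  ev <- best$ev
  cand <- if (!is.na(ev$idx) && length(best$candidates))
    best$candidates[[ev$idx]] else NULL
  lat <- best$latent
  copy_term <- if (!is.null(cand))
    sum(abs(lat$C_o - cand$C) / pmax(cand$C, 1)) else NA_real_
  euclid <- if (!is.null(cand))
    sqrt(sum((c(lat$L_o, lat$R_o) - c(cand$L, cand$R))^2)) else NA_real_
  list(candidate = cand, latent = lat,
       breakdown = list(delta_model = ev$dm, delta_data = ev$dd, F = ev$F,
                        copy_term = copy_term, euclid = euclid,
                        z1 = z1, n = ev$n, score = ev$score,
                        string = if (!is.null(cand)) cand$string else NA_character_,
                        copy_discrepancy = if (!is.null(cand)) cand$copy_discrepancy else NA_real_))
}

merge_latent <- function(latent, j, track, w, foldbacks, fb_map, z1) {
  b <- latent$boundaries
  labs <- b[j]:(b[j + 2L] - 1L)
  fb <- range_fb(foldbacks, fb_map, labs, z1)
  keep <- setdiff(seq_along(latent$C_o), j + 1L)
  out <- latent
  out$boundaries <- b[-(j + 1L)]
  for (f in c("C_o", "L_o", "R_o", "C_d", "L_d", "R_d"))
    out[[f]] <- latent[[f]][keep]
  out$C_o[j] <- out$C_d[j] <- range_cn(track, w, labs)
  out$L_o[j] <- out$L_d[j] <- fb[["L"]]
  out$R_o[j] <- out$R_d[j] <- fb[["R"]]
  out
}

# shift one internal boundary by a few labels, refreshing the two affected
# segments' data-derived values
shift_latent <- function(latent, bi, delta, track, w, foldbacks, fb_map, z1) {
  b <- latent$boundaries
  newb <- b[bi] + delta
  if (newb <= b[bi - 1L] || newb >= b[bi + 1L]) return(NULL)
  b[bi] <- newb
  out <- latent
  out$boundaries <- b
  for (seg in c(bi - 1L, bi)) {
    labs <- b[seg]:(b[seg + 1L] - 1L)
    fbv <- range_fb(foldbacks, fb_map, labs, z1)
    cnv <- range_cn(track, w, labs)
    out$C_o[seg] <- out$C_d[seg] <- cnv
    out$L_o[seg] <- out$L_d[seg] <- fbv[["L"]]
    out$R_o[seg] <- out$R_d[seg] <- fbv[["R"]]
  }
  out
}

split_latent <- function(latent, i, cut, track, w, foldbacks, fb_map, z1) {
  b <- latent$boundaries
  left <- b[i]:(cut - 1L); right <- cut:(b[i + 1L] - 1L)
  fbL <- range_fb(foldbacks, fb_map, left, z1)
  fbR <- range_fb(foldbacks, fb_map, right, z1)
  out <- latent
  out$boundaries <- sort(c(b, cut))
  ins <- function(v, at, vals) append(v[-at], vals, after = at - 1L)
  cn2 <- c(range_cn(track, w, left), range_cn(track, w, right))
  out$C_o <- ins(latent$C_o, i, cn2)
  out$C_d <- ins(latent$C_d, i, cn2)
  out$L_o <- ins(latent$L_o, i, c(fbL[["L"]], fbR[["L"]]))
  out$L_d <- ins(latent$L_d, i, c(fbL[["L"]], fbR[["L"]]))
  out$R_o <- ins(latent$R_o, i, c(fbL[["R"]], fbR[["R"]]))
  out$R_d <- ins(latent$R_d, i, c(fbL[["R"]], fbR[["R"]]))
  out
}
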