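# Ground-truth simulators: BFB positives via random cycle application, and
# ecDNA-like / chromothripsis-like negatives.  Structures are rendered
# directly at the (N, V, F_l, F_r) label abstraction by render_observed() --
# all downstream computation consumes only that tuple, so molecule-level
# simulation is not needed.

#' Simulation configuration for BFB positives
#'
#' @param tier `"simple"` (no fold-region deletions, no indels),
#'   `"intermediate"` (fold-region deletions), or `"complex"` (deletions and
#'   indels).
#' @param n_cycles number of BFB cycles applied after the initiating break;
#'   ignored when `target_cn` is given (cycles are then applied until the
#'   mean segment copy number reaches the target).
#' @param chrom,arm_start chromosome and centromere-proximal start of the
#'   simulated arm window (bp).
#' @param n_segments number of reference segments participating in the BFB
#'   derivation (1-7 in the study design).
#' @param seg_len_range uniform range of segment lengths (bp).
#' @param tail_len_range uniform range for the telomeric tail lost at the
#'   initiating break.
#' @param fold_del_prob probability that a fold junction carries flanking
#'   deletions (intermediate/complex tiers).
#' @param fold_del_mean mean of the exponential fold-deletion length (bp).
#' @param indel_rate per-segment probability of an internal indel (complex
#'   tier).
#' @param target_cn optional mean segment copy number to steer the random
#'   cycles towards (5-80 in the study design).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tier = c("simple", "intermediate", "complex"),
                       n_cycles = 4, chrom = "chr1", arm_start = 1e7,
                       n_segments = 3, seg_len_range = c(5e4, 3e5),
                       tail_len_range = c(2e5, 1e6),
                       fold_del_prob = 0.5, fold_del_mean = 2000,
                       indel_rate = 0.3, target_cn = NULL, seed = 1L) {
  tier <- match.arg(tier)
  structure(list(tier = tier, n_cycles = n_cycles, chrom = chrom,
                 arm_start = arm_start, n_segments = n_segments,
                 seg_len_range = seg_len_range,
                 tail_len_range = tail_len_range,
                 fold_del_prob = fold_del_prob,
                 fold_del_mean = fold_del_mean, indel_rate = indel_rate,
                 target_cn = target_cn, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a BFB-rearranged arm
#'
#' Applies random breakage-fusion-bridge cycles to a reference arm prefix:
#' the initiating break removes a telomeric tail, and each subsequent cycle
#' retains a random prefix of the string fused to its inverted copy.  When
#' `target_cn` is set, break lengths are drawn so that the total copy count
#' approaches `target_cn * n_segments` and the last cycle lands on it.
#' Intermediate/complex tiers add fold-region deletions (recorded as
#' junction offsets and copy-number nicks); the complex tier adds internal
#' indels.
#'
#' @param config a [sim_config()].
#' @return A list of class `bfb_sim`: `string` (ground-truth [bfb_string]),
#'   `vectors` (`C`, `L`, `R` recomputed from the final string), `arm`
#'   (reference segment table), and `structure` (the renderable
#'   [amplicon_structure] including the CN-1 centromeric flank and the CN-0
#'   lost tail).
#' @export
simulate_bfb <- function(config = sim_config()) {
  set.seed(config$seed)
  k <- config$n_segments
  if (k < 1L) stop("degenerate arm: at least 1 segment is required")
  seg_len <- round(runif(k, config$seg_len_range[1L], config$seg_len_range[2L]))
  tail_len <- round(runif(1, config$tail_len_range[1L], config$tail_len_range[2L]))
  bounds <- config$arm_start + cumsum(c(0, seg_len, tail_len))
  arm <- data.frame(segment = seq_len(k + 1L),
                    start = bounds[seq_len(k + 1L)],
                    end = bounds[-1L])
  # initiating break removes the tail; subsequent cycles grow the string
  s <- bfb_string(seq_len(k), rep(1L, k))
  lost_tail <- config$n_cycles > 0 || !is.null(config$target_cn)
  if (!is.null(config$target_cn)) {
    # draw derivations until the per-segment copy numbers stay in the
    # neighbourhood of the design range (balanced ladders, no runaway
    # single-segment amplification)
    cap <- max(100, 1.6 * config$target_cn)
    total_target <- config$target_cn * k
    best_s <- NULL
    for (try in seq_len(25L)) {
      s <- bfb_string(seq_len(k), rep(1L, k))
      for (cyc in seq_len(64L)) {
        len <- length(s)
        need <- total_target - len
        if (need <= 0) break
        d <- if (need <= len) max(1L, round(need)) else
          sample.int(len, 1L, prob = seq_len(len))  # prefer long extensions
        s <- apply_cycle(s, len + d)
        if (need <= len) break
      }
      if (is.null(best_s) ||
          max(count_vector(s, k)) < max(count_vector(best_s, k)))
        best_s <- s
      if (max(count_vector(s, k)) <= cap) { best_s <- s; break }
    }
    s <- best_s
  } else if (config$n_cycles > 0) {
    for (cyc in seq_len(config$n_cycles)) {
      len <- length(s)
      s <- apply_cycle(s, len + sample.int(len, 1L))
    }
  }
  if (!lost_tail) arm <- arm[seq_len(k), , drop = FALSE]
  n_arm <- nrow(arm)
  C <- count_vector(s, n_arm)
  fb <- foldback_vectors(s, n_arm)

  # junctions: right folds sit at segment ends, left folds at segment starts
  jn <- data.frame(pos = numeric(), side = character(),
                   multiplicity = integer(), del_a = numeric(),
                   del_b = numeric())
  for (i in seq_len(k)) {
    if (fb$R[i] > 0)
      jn <- rbind(jn, data.frame(pos = arm$end[i], side = "right",
                                 multiplicity = fb$R[i], del_a = 0, del_b = 0))
    if (fb$L[i] > 0)
      jn <- rbind(jn, data.frame(pos = arm$start[i], side = "left",
                                 multiplicity = fb$L[i], del_a = 0, del_b = 0))
  }
  nicks <- NULL
  if (config$tier %in% c("intermediate", "complex") && nrow(jn)) {
    # fold-region deletions separate the aligned foldback ends; the
    # copy-number track is reported at segment resolution upstream, so the
    # deletions manifest in the junction coordinates, not as CN dips
    for (r in seq_len(nrow(jn))) {
      if (runif(1) < config$fold_del_prob) {
        jn$del_a[r] <- round(rexp(1, 1 / config$fold_del_mean))
        jn$del_b[r] <- round(rexp(1, 1 / config$fold_del_mean))
      }
    }
  }
  if (config$tier == "complex") {
    # internal indels: shallow local copy-number nicks
    for (i in seq_len(k)) {
      if (C[i] >= 2 && runif(1) < config$indel_rate) {
        len <- round(runif(1, 1e4, 5e4))
        at <- runif(1, arm$start[i], max(arm$start[i], arm$end[i] - len))
        lost <- sample.int(min(2L, C[i] - 1L), 1L)
        nicks <- rbind(nicks, data.frame(start = at, end = at + len,
                                         loss = lost))
      }
    }
  }

  flank_len <- 5e5
  segments <- data.frame(
    start = c(config$arm_start - flank_len, arm$start),
    end = c(config$arm_start, arm$end),
    cn = c(1, C[seq_len(k)], if (lost_tail) 0))
  junctions <- if (nrow(jn)) {
    data.frame(pos_a = jn$pos - ifelse(jn$side == "right", jn$del_a, -jn$del_a),
               pos_b = jn$pos - ifelse(jn$side == "right", jn$del_b, -jn$del_b),
               side = jn$side, multiplicity = jn$multiplicity)
  } else {
    data.frame(pos_a = numeric(), pos_b = numeric(), side = character(),
               multiplicity = integer())
  }
  structure(list(
    string = s, vectors = list(C = C, L = fb$L, R = fb$R), arm = arm,
    tier = config$tier, config = config,
    structure = amplicon_structure(config$chrom, segments, junctions,
                                   nicks = nicks)),
    class = "bfb_sim")
}

#' Renderable amplicon structure
#'
#' A piecewise-constant copy-number profile plus foldback junctions with
#' multiplicities, the common ground-truth representation for positives and
#' negatives.
#'
#' @param chrom chromosome.
#' @param segments data.frame `start`, `end`, `cn` (contiguous, reference
#'   order).
#' @param junctions data.frame `pos_a`, `pos_b`, `side`, `multiplicity`.
#' @param nicks optional data.frame `start`, `end`, `loss`: intervals where
#'   `loss` copies are locally missing (fold-region deletions, indels).
#' @return A list of class `amplicon_structure`.
#' @export
amplicon_structure <- function(chrom, segments, junctions, nicks = NULL) {
  stopifnot(all(diff(segments$start) > 0), all(segments$cn >= 0))
  structure(list(chrom = chrom, segments = segments, junctions = junctions,
                 nicks = nicks), class = "amplicon_structure")
}

#' Simulate a non-BFB focal amplification
#'
#' Negative ground truths for benchmarking.  `"ecdna"` builds a circular
#' arrangement of 1-10 arm segments amplified to a high copy number; the
#' native locus keeps one chromosomal copy, so the rendered profile is the
#' amplified intervals on a CN-1 background with no telomeric loss.
#' Duplication-inversions inside the circle create genuine foldback
#' junctions (`dup_inv`).  `"chromothripsis"` shatters a region, retains a
#' random subset of pieces at moderate copy number, and emits foldback-like
#' junctions at a subset of piece boundaries.
#'
#' @param kind `"ecdna"` or `"chromothripsis"`.
#' @param params list of overrides: `n_segments`, `cn`, `dup_inv`
#'   (`"none"`, `"one_side"`, `"both"`, `"random"`) for ecdna;
#'   `n_pieces`, `base_cn`, `fb_prob` for chromothripsis; common: `chrom`,
#'   `locus_start`, `seg_len_range`.
#' @param seed integer seed.
#' @return A list of class `neg_sim` with the ground truth and a renderable
#'   `structure`.
#' @export
simulate_negative <- function(kind = c("ecdna", "chromothripsis"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  p <- modifyList(list(chrom = "chr1", locus_start = 1e7,
                       seg_len_range = c(5e4, 3e5)), params)
  flank <- 5e5
  if (kind == "ecdna") {
    n_seg <- if (!is.null(p$n_segments)) p$n_segments else sample.int(10L, 1L)
    cn <- if (!is.null(p$cn)) p$cn else sample(10:100, 1L)
    dup_inv <- if (!is.null(p$dup_inv)) p$dup_inv else "random"
    seg_len <- round(runif(n_seg, p$seg_len_range[1L], p$seg_len_range[2L]))
    bounds <- p$locus_start + cumsum(c(0, seg_len))
    segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
                       cn = 1 + cn)
    segs <- rbind(data.frame(start = p$locus_start - flank,
                             end = p$locus_start, cn = 1),
                  segs,
                  data.frame(start = max(bounds), end = max(bounds) + flank,
                             cn = 1))
    jn <- data.frame(pos_a = numeric(), pos_b = numeric(), side = character(),
                     multiplicity = integer())
    add_fold <- function(jn, pos, side)
      rbind(jn, data.frame(pos_a = pos, pos_b = pos, side = side,
                           multiplicity = cn))
    if (dup_inv == "both" || (dup_inv == "random" && runif(1) < 0.5)) {
      # duplication-inversion: fold at a segment end (and possibly both ends)
      i <- sample.int(n_seg, 1L)
      jn <- add_fold(jn, bounds[i + 1L], "right")
      if (dup_inv == "both" || runif(1) < 0.5)
        jn <- add_fold(jn, bounds[i], "left")
    } else if (dup_inv == "one_side") {
      i <- sample.int(n_seg, 1L)
      jn <- add_fold(jn, bounds[i + 1L], sample(c("left", "right"), 1L))
    }
    truth <- list(kind = kind, n_segments = n_seg, cn = cn, dup_inv = dup_inv)
  } else {
    n_pieces <- if (!is.null(p$n_pieces)) p$n_pieces else sample(6:14, 1L)
    base_cn <- if (!is.null(p$base_cn)) p$base_cn else sample(5:12, 1L)
    fb_prob <- if (!is.null(p$fb_prob)) p$fb_prob else 0.4
    seg_len <- round(runif(n_pieces, p$seg_len_range[1L], p$seg_len_range[2L]))
    bounds <- p$locus_start + cumsum(c(0, seg_len))
    piece_cn <- ifelse(runif(n_pieces) < 0.7,
                       pmax(1, base_cn + sample(-2:2, n_pieces, replace = TRUE)),
                       sample(0:1, n_pieces, replace = TRUE))
    segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
                       cn = 1 + piece_cn)
    segs <- rbind(data.frame(start = p$locus_start - flank,
                             end = p$locus_start, cn = 1),
                  segs,
                  data.frame(start = max(bounds), end = max(bounds) + flank,
                             cn = 1))
    jn <- data.frame(pos_a = numeric(), pos_b = numeric(), side = character(),
                     multiplicity = integer())
    for (i in seq_len(n_pieces)) {
      if (piece_cn[i] >= 2 && runif(1) < fb_prob) {
        side <- sample(c("left", "right"), 1L)
        pos <- if (side == "right") bounds[i + 1L] else bounds[i]
        jn <- rbind(jn, data.frame(pos_a = pos, pos_b = pos, side = side,
                                   multiplicity = max(1L, rpois(1, piece_cn[i] / 2))))
      }
    }
    truth <- list(kind = kind, n_pieces = n_pieces, base_cn = base_cn,
                  piece_cn = piece_cn)
  }
  structure(list(kind = kind, truth = truth,
                 structure = amplicon_structure(p$chrom, segs, jn)),
            class = "neg_sim")
}

#' Rendering configuration
#'
#' @param z1 mean molecules per copy per label (coverage scale).
#' @param label_spacing_bp mean inter-label spacing (exponential, floored at
#'   `min_spacing_bp`).
#' @param min_spacing_bp minimum spacing between labels.
#' @param boundary_mode `"sharp"` (exact per-segment copy numbers) or
#'   `"gradual"` (running-mean ramp across `ramp_labels` labels, as segment
#'   boundaries appear in real data).
#' @param ramp_labels ramp width in labels for gradual mode.
#' @param dropout probability that a molecule supporting a foldback junction
#'   is not detected.
#' @param noise `"called"` (default: `N` mimics an upstream copy-number
#'   caller -- piecewise smooth with a per-segment relative bias of
#'   `cn_bias_sd` and small per-label wobble of `cn_label_sd`),
#'   `"poisson"` (raw `N = V / z1`), or `"none"` (exact rendering).
#'   Coverage `V ~ Poisson(z1 * cn)` in all stochastic modes.
#' @param cn_bias_sd relative per-segment bias of the called copy number.
#' @param cn_label_sd absolute per-label wobble of the called copy number.
#' @param seed integer seed.
#' @return A list of class `render_config`.
#' @export
render_config <- function(z1 = 100, label_spacing_bp = 5000,
                          min_spacing_bp = 500,
                          boundary_mode = c("sharp", "gradual"),
                          ramp_labels = 5, dropout = 0.05,
                          noise = c("called", "poisson", "none"),
                          cn_bias_sd = 0, cn_label_sd = 0.1, seed = 1L) {
  boundary_mode <- match.arg(boundary_mode)
  noise <- match.arg(noise)
  stopifnot(z1 > 0, dropout >= 0, dropout <= 1)
  structure(list(z1 = z1, label_spacing_bp = label_spacing_bp,
                 min_spacing_bp = min_spacing_bp,
                 boundary_mode = boundary_mode, ramp_labels = ramp_labels,
                 dropout = dropout, noise = noise,
                 cn_bias_sd = cn_bias_sd, cn_label_sd = cn_label_sd,
                 seed = as.integer(seed)),
            class = "render_config")
}

#' Render a ground-truth structure as observed label data
#'
#' Places labels along the reference span of the structure, draws per-label
#' molecule coverage `V ~ Poisson(z1 * local copy number)` (or exact counts
#' for noiseless rendering), reports `N = V / z1`, and converts every
#' ground-truth foldback junction into a [foldback_set] record whose
#' supporting molecule count is `Binomial(z1 * multiplicity, 1 - dropout)`.
#' Gradual boundary mode convolves the copy-number profile with a
#' running-mean ramp before sampling.
#'
#' @param structure an [amplicon_structure] (or a `bfb_sim` / `neg_sim`,
#'   whose `$structure` is used).
#' @param render a [render_config()].
#' @return `list(track = label_track, foldbacks = foldback_set)`.
#' @export
render_observed <- function(structure, render = render_config()) {
  if (inherits(structure, c("bfb_sim", "neg_sim")))
    structure <- structure$structure
  stopifnot(inherits(structure, "amplicon_structure"))
  set.seed(render$seed)
  segs <- structure$segments
  span <- c(min(segs$start), max(segs$end))
  gaps <- pmax(render$min_spacing_bp,
               round(rexp(ceiling(diff(span) / render$min_spacing_bp),
                          1 / render$label_spacing_bp)))
  pos <- span[1L] + cumsum(gaps)
  pos <- pos[pos < span[2L]]
  cn <- segs$cn[findInterval(pos, segs$start)]
  if (!is.null(structure$nicks)) {
    for (r in seq_len(nrow(structure$nicks))) {
      hit <- pos >= structure$nicks$start[r] & pos < structure$nicks$end[r]
      cn[hit] <- pmax(0, cn[hit] - structure$nicks$loss[r])
    }
  }
  if (render$boundary_mode == "gradual" && length(cn) > render$ramp_labels) {
    k <- max(3L, render$ramp_labels %/% 2L * 2L + 1L)
    pad <- c(rep(cn[1L], k %/% 2L), cn, rep(cn[length(cn)], k %/% 2L))
    cn <- as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))[
      (k %/% 2L + 1L):(k %/% 2L + length(pos))]
  }
  z1 <- render$z1
  if (render$noise == "none") {
    V <- round(z1 * cn)
    N <- V / z1
  } else if (render$noise == "poisson") {
    V <- rpois(length(cn), z1 * cn)
    N <- V / z1
  } else {
    # "called": N mimics an upstream CN caller -- smooth within segments,
    # with a per-segment relative bias and small per-label wobble
    V <- rpois(length(cn), z1 * cn)
    seg_id <- cumsum(c(TRUE, abs(diff(cn)) > 1e-9))
    bias <- stats::rnorm(max(seg_id), 0, render$cn_bias_sd)
    N <- pmax(0, cn * (1 + bias[seg_id]) +
                stats::rnorm(length(cn), 0, render$cn_label_sd))
  }
  track <- label_track(structure$chrom, pos, V, N)
  jn <- structure$junctions
  mol_counter <- 0L
  keep <- list()
  if (nrow(jn)) {
    for (r in seq_len(nrow(jn))) {
      size <- round(z1 * jn$multiplicity[r])
      nmol <- if (render$noise == "none" && render$dropout == 0) size
              else rbinom(1L, size, 1 - render$dropout)
      if (nmol < 1L) next
      ids <- sprintf("m%07d", mol_counter + seq_len(nmol))
      mol_counter <- mol_counter + nmol
      keep[[length(keep) + 1L]] <-
        data.frame(chrom = structure$chrom,
                   pos_a = min(jn$pos_a[r], jn$pos_b[r]),
                   pos_b = max(jn$pos_a[r], jn$pos_b[r]),
                   side = jn$side[r], molecules = I(list(ids)))
    }
  }
  fb <- if (length(keep)) {
    df <- do.call(rbind, keep)
    foldback_set(df$chrom, df$pos_a, df$pos_b, df$side, df$molecules)
  } else foldback_set()
  list(track = track, foldbacks = fb)
}
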