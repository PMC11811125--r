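# Candidate-region selection: amplified labels with a foldback excess are
# linked into regions by distance / copy-number rules.

# Map each foldback junction endpoint to a label on the same chromosome
# within `window` bp.  Assignment is directional: the molecules supporting a
# right foldback cover the sequence centromeric of the junction (the label
# at or before it), a left foldback the sequence telomeric of it (the label
# at or after), which keeps junctions that sit exactly on a copy-number
# boundary attached to the segment that carries them.  Returns a data.frame
# (record, label) with one row per assigned endpoint.
assign_foldbacks <- function(track, foldbacks, window = 5e4) {
  if (nrow(foldbacks) == 0L)
    return(data.frame(record = integer(), label = integer()))
  rec <- integer(); lab <- integer()
  for (ch in unique(foldbacks$chrom)) {
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    pos <- track$pos[ti]
    fi <- which(foldbacks$chrom == ch)
    for (col in c("pos_a", "pos_b")) {
      p <- foldbacks[[col]][fi]
      right <- foldbacks$side[fi] == "right"
      at_or_before <- findInterval(p, pos)               # 0 if before first
      at_or_after <- findInterval(p - 0.5, pos) + 1L     # n+1 if after last
      pick <- ifelse(right, at_or_before, at_or_after)
      # fall back to the other side when no label exists in that direction
      pick[pick == 0L] <- 1L
      pick[pick > length(pos)] <- length(pos)
      d <- abs(p - pos[pick])
      keep <- d <= window
      rec <- c(rec, fi[keep])
      lab <- c(lab, ti[pick[keep]])
    }
  }
  unique(data.frame(record = rec, label = lab))
}

# Per-label count of distinct supporting molecules over all assigned records.
label_foldback_support <- function(track, foldbacks, window = 5e4) {
  support <- numeric(nrow(track))
  amap <- assign_foldbacks(track, foldbacks, window)
  if (nrow(amap)) {
    by_label <- split(amap$record, amap$label)
    counts <- vapply(by_label, function(recs)
      length(unique(unlist(foldbacks$molecules[recs]))), 0L)
    support[as.integer(names(by_label))] <- counts
  }
  support
}

#' Select candidate labels for BFB screening
#'
#' A label is selected iff its called copy number exceeds `cn_min` (strictly)
#' and its foldback-supporting molecule count exceeds `fb_excess` times the
#' genome-wide mean per-label support -- amplification plus a foldback
#' excess, the joint signature of BFB.
#'
#' @param track a [label_track] (may span several chromosomes).
#' @param foldbacks a [foldback_set].
#' @param cn_min strict copy-number threshold (default 3).
#' @param fb_excess enrichment factor over the mean (default 1.1).
#' @param fb_window_bp junction-to-label assignment window (default 5e4).
#' @return Integer row indices of selected labels, with the per-label support
#'   vector attached as attribute `support`.
#' @export
select_labels <- function(track, foldbacks, cn_min = 3, fb_excess = 1.1,
                          fb_window_bp = 5e4) {
  support <- label_foldback_support(track, foldbacks, fb_window_bp)
  sel <- which(track$cn > cn_min & support > fb_excess * mean(support))
  attr(sel, "support") <- support
  sel
}

#' Link selected labels into candidate regions
#'
#' Consecutive selected labels on the same chromosome are linked iff their
#' distance `D` is below `link_dist_bp` or the mean copy number `E` of the
#' pair exceeds `link_cn`; single-linkage transitive closure then defines the
#' candidate regions.  Region bounds are the min/max linked label positions
#' (end exclusive).
#'
#' @param selected integer label indices from [select_labels()], sorted by
#'   position within chromosome.
#' @param track the [label_track] the indices refer to.
#' @param link_dist_bp distance threshold in bp (default 1.5e6).
#' @param link_cn copy-number threshold (default 7).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, and a list column `labels` of member label indices.
#' @export
link_and_cluster <- function(selected, track, link_dist_bp = 1.5e6,
                             link_cn = 7) {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    name = character(), stringsAsFactors = FALSE)
  out$labels <- list()
  if (!length(selected)) return(out)
  selected <- selected[order(track$chrom[selected], track$pos[selected])]
  k <- 0L
  for (ch in unique(track$chrom[selected])) {
    si <- selected[track$chrom[selected] == ch]
    pos <- track$pos[si]; cn <- track$cn[si]
    if (length(si) > 1L) {
      d <- diff(pos)
      e <- (cn[-length(cn)] + cn[-1L]) / 2
      linked <- d < link_dist_bp | e > link_cn
      grp <- cumsum(c(TRUE, !linked))
    } else grp <- 1L
    for (g in split(seq_along(si), grp)) {
      k <- k + 1L
      row <- data.frame(chrom = ch, start = min(pos[g]),
                        end = max(pos[g]) + 1, name = paste0("region_", k),
                        stringsAsFactors = FALSE)
      row$labels <- list(si[g])
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
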