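# Stylized reconstruction rendering: genomic coordinates on x, copy number
# on y, per-segment bars, a foldback track, and the traversal path of the
# collapsed core structure with its repeat multiplicity.

# smallest repeated unit of the string's maximal tandem repetition
# (maximises reps * period over all start positions and periods, reps >= 2;
# the smallest unit among maximal covers wins)
core_structure <- function(s) {
  s <- as_bfb(s)
  n <- length(s$seg)
  key <- paste0(s$seg, ifelse(s$dir > 0, "+", "-"))
  best <- list(len = 0L, period = 0L, start = 0L, reps = 0L)
  for (period in seq_len(n %/% 2L)) {
    for (start in seq_len(n - 2L * period + 1L)) {
      reps <- 1L
      while (start + (reps + 1L) * period - 1L <= n &&
             all(key[start:(start + period - 1L)] ==
                   key[(start + reps * period):(start + (reps + 1L) * period - 1L)]))
        reps <- reps + 1L
      cover <- reps * period
      if (reps >= 2L && (cover > best$len ||
                         (cover == best$len && period < best$period))) {
        best <- list(len = cover, period = period, start = start, reps = reps)
      }
    }
  }
  if (best$len == 0L) return(NULL)
  idx <- best$start:(best$start + best$period - 1L)
  list(unit = paste0(key[idx], collapse = ""), multiplicity = best$reps,
       start = best$start, period = best$period)
}

svg_el <- function(tag, ..., content = NULL) {
  at <- list(...)
  attrs <- paste0(names(at), '="', unlist(at), '"', collapse = " ")
  if (is.null(content)) paste0("<", tag, " ", attrs, "/>")
  else paste0("<", tag, " ", attrs, ">", content, "</", tag, ">")
}

#' Stylized SVG rendering of a BFB reconstruction
#'
#' Draws the fitted amplicon: orange per-segment copy-number bars over
#' genomic coordinates, a foldback track with left/right arrow glyphs, and
#' the reconstruction string with its core structure collapsed to
#' `unit x multiplicity` when the architecture is a long tandem repetition.
#'
#' @param fit a BFB-positive [bfb_fit].
#' @param width,height canvas size in px.
#' @return A single string containing the SVG document.
#' @export
render_reconstruction <- function(fit, width = 900, height = 420) {
  if (!inherits(fit, "bfb_fit") || fit$classification != "BFB_positive")
    stop("render_reconstruction() needs a BFB-positive bfb_fit")
  seg <- fit$segments
  C <- fit$C; L <- fit$L; R <- fit$R
  x0 <- min(seg$start); x1 <- max(seg$end)
  sx <- function(p) 60 + (p - x0) / (x1 - x0) * (width - 90)
  ymax <- max(C, 1)
  sy <- function(cn) height - 90 - cn / ymax * (height - 190)
  parts <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                     width, height),
             svg_el("rect", x = 0, y = 0, width = width, height = height,
                    fill = "white"))
  # axes
  parts <- c(parts,
             svg_el("line", x1 = 60, y1 = sy(0), x2 = width - 30, y2 = sy(0),
                    stroke = "black"),
             svg_el("line", x1 = 60, y1 = sy(0), x2 = 60, y2 = sy(ymax),
                    stroke = "black"),
             svg_el("text", x = 15, y = sy(ymax / 2), `font-size` = 12,
                    transform = sprintf("rotate(-90 15 %0.1f)", sy(ymax / 2)),
                    content = "copy number"),
             svg_el("text", x = width / 2, y = height - 55, `font-size` = 12,
                    content = sprintf("%s:%s-%s", seg$chrom[1L],
                                      format(x0, scientific = FALSE),
                                      format(x1, scientific = FALSE))))
  # segment bars (nonzero copy number)
  for (i in seq_len(nrow(seg))) {
    if (C[i] <= 0) next
    parts <- c(parts,
               svg_el("rect", class = "segment-bar",
                      x = sprintf("%.1f", sx(seg$start[i])),
                      y = sprintf("%.1f", sy(C[i])),
                      width = sprintf("%.1f", sx(seg$end[i]) - sx(seg$start[i])),
                      height = sprintf("%.1f", sy(0) - sy(C[i])),
                      fill = "orange", stroke = "darkorange"),
               svg_el("text", x = sprintf("%.1f", (sx(seg$start[i]) + sx(seg$end[i])) / 2),
                      y = sprintf("%.1f", sy(C[i]) - 4), `font-size` = 11,
                      `text-anchor` = "middle", content = C[i]))
  }
  # foldback track on a yellow band
  fy <- height - 80
  parts <- c(parts,
             svg_el("rect", x = 60, y = fy - 12, width = width - 90,
                    height = 24, fill = "lightyellow"))
  for (i in seq_len(nrow(seg))) {
    if (R[i] > 0)
      parts <- c(parts,
                 svg_el("path", class = "foldback-right",
                        d = sprintf("M %.1f %.1f l -14 0 m 0 -4 l 6 4 l -6 4",
                                    sx(seg$end[i]), fy),
                        stroke = "navy", fill = "none", `stroke-width` = 1.5),
                 svg_el("text", x = sprintf("%.1f", sx(seg$end[i]) - 18),
                        y = fy - 4, `font-size` = 10, fill = "navy",
                        `text-anchor` = "end", content = paste0("R=", R[i])))
    if (L[i] > 0)
      parts <- c(parts,
                 svg_el("path", class = "foldback-left",
                        d = sprintf("M %.1f %.1f l 14 0 m 0 -4 l -6 4 l 6 4",
                                    sx(seg$start[i]), fy),
                        stroke = "navy", fill = "none", `stroke-width` = 1.5),
                 svg_el("text", x = sprintf("%.1f", sx(seg$start[i]) + 18),
                        y = fy - 4, `font-size` = 10, fill = "navy",
                        content = paste0("L=", L[i])))
  }
  # architecture string, with the core structure collapsed
  core <- core_structure(fit$string)
  label <- if (is.null(core)) fit$string else {
    key <- fit$string
    sprintf("%s  [core %s x %d]", key, core$unit, core$multiplicity)
  }
  parts <- c(parts,
             svg_el("rect", x = 60, y = 12, width = width - 90, height = 26,
                    fill = "#eef3ff", stroke = "steelblue"),
             svg_el("text", x = 70, y = 30, `font-size` = 12, fill = "navy",
                    class = "architecture", content = label),
             svg_el("text", x = width - 35, y = 30, `font-size` = 12,
                    `text-anchor` = "end",
                    content = sprintf("score %.3f", fit$score)))
  paste0(c(parts, "</svg>"), collapse = "\n")
}

#' @describeIn bfb_fit base-graphics version of the stylized reconstruction.
#' @param x,y,... standard plot-method arguments (`y` ignored).
#' @export
plot.bfb_fit <- function(x, y, ...) {
  if (is.null(x$segments)) stop("nothing to plot: the fit was filtered")
  seg <- x$segments
  C <- if (!is.null(x$C)) x$C else round(seg$C_o)
  ymax <- max(C, seg$C_o, 1)
  graphics::plot(NA, xlim = range(c(seg$start, seg$end)),
                 ylim = c(-ymax * 0.15, ymax * 1.15),
                 xlab = sprintf("%s position (bp)", seg$chrom[1L]),
                 ylab = "copy number",
                 main = sprintf("%s (score %.3f)", x$classification, x$score))
  for (i in seq_len(nrow(seg))) {
    graphics::rect(seg$start[i], 0, seg$end[i], C[i], col = "orange",
                   border = "darkorange")
    if (!is.null(x$R) && x$R[i] > 0)
      graphics::arrows(seg$end[i], -ymax * 0.08, seg$end[i] - 0.3 *
                         (seg$end[i] - seg$start[i]), -ymax * 0.08,
                       length = 0.08, col = "navy")
    if (!is.null(x$L) && x$L[i] > 0)
      graphics::arrows(seg$start[i], -ymax * 0.12, seg$start[i] + 0.3 *
                         (seg$end[i] - seg$start[i]), -ymax * 0.12,
                       length = 0.08, col = "navy")
  }
  graphics::lines(c(rbind(seg$start, seg$end)), rep(seg$C_o, each = 2),
                  col = "steelblue", lwd = 2)
  if (!is.na(x$string))
    graphics::mtext(x$string, side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}
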