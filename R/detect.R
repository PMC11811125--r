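# Genome-wide detection pipeline and the JSON report.

#' Detect BFB amplicons genome-wide
#'
#' Runs the full pipeline: candidate labels are selected by amplification
#' and foldback excess, linked into regions, and every region is fitted
#' with [bfb_fit()].  Per-region failures are caught and reported without
#' aborting the run.  Deterministic under a fixed seed.
#'
#' @param track a [label_track].
#' @param foldbacks a [foldback_set].
#' @param params a [bfb_params].
#' @param seed master seed (per-region seeds derive from it).
#' @return An object of class `bfb_detect_report`: `regions` (the candidate
#'   region table), `fits` (list of [bfb_fit] objects or error records),
#'   `params`, `seed`.
#' @export
detect <- function(track, foldbacks, params = bfb_params(),
                   seed = params$seed) {
  seed <- as.integer(seed)
  sel <- select_labels(track, foldbacks, params$cn_min, params$fb_excess,
                       params$fb_window_bp)
  regions <- link_and_cluster(sel, track, params$link_dist_bp, params$link_cn)
  fits <- lapply(seq_len(nrow(regions)), function(i) {
    tryCatch(
      bfb_fit(track, foldbacks,
              region = regions[i, c("chrom", "start", "end")],
              params = params, seed = seed + i),
      error = function(e) {
        structure(list(region = as.list(regions[i, c("chrom", "start", "end")]),
                       classification = "error", score = NA_real_,
                       error = conditionMessage(e)),
                  class = "bfb_fit_error")
      })
  })
  structure(list(regions = regions, fits = fits, params = params,
                 seed = seed, version = as.character(utils::packageVersion("bfbscope"))),
            class = "bfb_detect_report")
}

#' @export
print.bfb_detect_report <- function(x, ...) {
  cat("<bfb_detect_report> ", nrow(x$regions), " candidate region(s)\n",
      sep = "")
  for (f in x$fits) {
    if (inherits(f, "bfb_fit_error")) {
      cat("  ", f$region$chrom, ": error: ", f$error, "\n", sep = "")
    } else {
      cat(sprintf("  %s:%s-%s  %s  score %.3f\n", f$region$chrom,
                  format(f$region$start, scientific = FALSE),
                  format(f$region$end, scientific = FALSE),
                  f$classification, f$score))
    }
  }
  invisible(x)
}

#' Write / read a detection report as JSON
#'
#' The JSON round-trip preserves every per-region record: region,
#' classification, score, breakdown, architecture string, `(C, L, R)`,
#' fitted segments, parameters and seed.
#'
#' @param report a [detect()] result.
#' @param path output path.
#' @return `path` (write) or the parsed report list (read).
#' @export
write_report <- function(report, path) {
  recs <- lapply(report$fits, function(f) {
    if (inherits(f, "bfb_fit_error"))
      return(list(region = f$region, classification = "error",
                  error = f$error))
    list(region = f$region, classification = f$classification,
         score = f$score, string = f$string,
         C = f$C, L = f$L, R = f$R,
         segments = f$segments, breakdown = f$breakdown[
           c("delta_model", "delta_data", "F", "n", "z1")],
         orientation = f$orientation, seed = f$seed)
  })
  obj <- list(version = report$version, seed = report$seed,
              params = unclass(report$params), records = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
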