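#' Label tracks
#'
#' A label track is the copy-number side of the optical-map abstraction: an
#' ordered set of genomic label positions, each with its raw molecule
#' coverage `V` and called copy number `N`.  It is stored as a data.frame
#' with columns `chrom`, `pos` (0-based bp), `coverage`, `cn`, sorted by
#' `(chrom, pos)`.
#'
#' @param chrom chromosome name(s).
#' @param pos 0-based label positions (bp).
#' @param coverage per-label raw molecule coverage `V` (>= 0).
#' @param cn per-label called copy number `N` (>= 0).
#' @return A data.frame of class `label_track`.
#' @export
label_track <- function(chrom, pos, coverage, cn) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   coverage = as.numeric(coverage), cn = as.numeric(cn),
                   stringsAsFactors = FALSE)
  validate_track(df)
}

validate_track <- function(df, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  need <- c("chrom", "pos", "coverage", "cn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("label track is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$pos) | df$pos < 0 | df$pos != floor(df$pos))
  if (length(bad)) stop("invalid position at ", where(bad[1L]))
  bad <- which(is.na(df$cn) | df$cn < 0)
  if (length(bad)) stop("negative or missing copy number at ", where(bad[1L]))
  bad <- which(is.na(df$coverage) | df$coverage < 0)
  if (length(bad)) stop("negative or missing coverage at ", where(bad[1L]))
  ord <- order(df$chrom, df$pos)
  if (!is.null(lines)) lines <- lines[ord]
  df <- df[ord, , drop = FALSE]
  dup <- which(duplicated(df[, c("chrom", "pos")]))
  if (length(dup)) stop("duplicate label position at ", where(dup[1L]))
  rownames(df) <- NULL
  class(df) <- c("label_track", "data.frame")
  df
}

#' Read a label track from TSV
#'
#' Expects a header with columns `chrom`, `pos`, `coverage`, `cn`; positions
#' are 0-based integers.  Rows are validated and sorted; format errors name
#' the offending line.
#'
#' @param path file path.
#' @return A [label_track] data.frame.
#' @export
read_label_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_track(df, lines = seq_len(nrow(df)) + 1L)
}

#' @rdname read_label_track
#' @param track a [label_track].
#' @export
write_label_track <- function(track, path) {
  write.table(as.data.frame(track)[, c("chrom", "pos", "coverage", "cn")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Foldback junction records
#'
#' A foldback joins a genomic position to a nearby position in inverted
#' orientation.  `side` is `"right"` when the copy folds back at its
#' telomeric end (reference-then-inverted) and `"left"` for the mirror case.
#' Each record carries the identifiers of the molecules supporting the
#' junction; molecule sets are deduplicated by union when aggregated.
#'
#' @param chrom,pos_a,pos_b,side,molecules record fields; `molecules` is a
#'   list of character vectors.  `pos_a > pos_b` is normalised by swapping
#'   (with a warning).
#' @return A data.frame of class `foldback_set` with a `molecules` list
#'   column.
#' @export
foldback_set <- function(chrom = character(), pos_a = numeric(),
                         pos_b = numeric(), side = character(),
                         molecules = list()) {
  df <- data.frame(chrom = as.character(chrom), pos_a = as.numeric(pos_a),
                   pos_b = as.numeric(pos_b), side = as.character(side),
                   stringsAsFactors = FALSE)
  df$molecules <- molecules
  validate_foldbacks(df)
}

validate_foldbacks <- function(df, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  bad <- which(!df$side %in% c("left", "right"))
  if (length(bad))
    stop("unknown foldback side '", df$side[bad[1L]], "' at ", where(bad[1L]))
  nmol <- vapply(df$molecules, length, 0L)
  if (any(nmol == 0L))
    stop("empty molecule list at ", where(which(nmol == 0L)[1L]))
  sw <- which(df$pos_a > df$pos_b)
  if (length(sw)) {
    warning("swapped pos_a/pos_b normalised for ", length(sw), " record(s)")
    tmp <- df$pos_a[sw]; df$pos_a[sw] <- df$pos_b[sw]; df$pos_b[sw] <- tmp
  }
  rownames(df) <- NULL
  class(df) <- c("foldback_set", "data.frame")
  df
}

#' Read foldback records from TSV
#'
#' Expects header columns `chrom`, `pos_a`, `pos_b`, `side` (`left`/`right`)
#' and `molecule_ids` (comma-joined identifiers).
#'
#' @param path file path.
#' @return A [foldback_set].
#' @export
read_foldbacks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = list(molecule_ids = "character"))
  need <- c("chrom", "pos_a", "pos_b", "side", "molecule_ids")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("foldback table is missing column(s): ", paste(miss, collapse = ", "))
  df$molecules <- strsplit(df$molecule_ids, ",", fixed = TRUE)
  df$molecules <- lapply(df$molecules, function(x) x[nzchar(x)])
  df$molecule_ids <- NULL
  validate_foldbacks(df, lines = seq_len(nrow(df)) + 1L)
}

#' @rdname read_foldbacks
#' @param fb a [foldback_set].
#' @export
write_foldbacks <- function(fb, path) {
  out <- data.frame(chrom = fb$chrom, pos_a = fb$pos_a, pos_b = fb$pos_b,
                    side = fb$side,
                    molecule_ids = vapply(fb$molecules, paste, "",
                                          collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED3+name
#'
#' @param regions a region table from [link_and_cluster()].
#' @param path file path.
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = regions$name, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
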