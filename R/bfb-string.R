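#' BFB strings
#'
#' A BFB string encodes the architecture of a rearranged chromosome arm as a
#' sequence of oriented reference segments, written centromere to telomere.
#' Segment indices start at 1 at the centromeric end; orientation `+` is
#' reference orientation, `-` inverted.  The text encoding concatenates index
#' and orientation, e.g. `"1+2+3+3-2-"`.
#'
#' A well-formed string starts with `1+` (the centromeric anchor) and uses a
#' prefix `{1..k}` of the segment indices.  Whether a well-formed string is
#' *obtainable by BFB cycles* is decided by [is_bfb_string()].
#'
#' @param seg integer vector of segment indices (>= 1).
#' @param dir integer vector of orientations, `+1` or `-1` (alternatively a
#'   character vector of `"+"`/`"-"`).
#' @return An object of class `bfb_string`.
#' @examples
#' s <- bfb_string(c(1, 2, 3), c(1, 1, 1))
#' format(s)
#' parse_bfb("1+2+3+3-2-")
#' @seealso [apply_cycle()], [count_vector()], [foldback_vectors()],
#'   [is_bfb_string()]
#' @export
bfb_string <- function(seg, dir) {
  if (is.character(dir)) dir <- ifelse(dir == "+", 1L, -1L)
  seg <- as.integer(seg)
  dir <- as.integer(dir)
  if (length(seg) == 0L) stop("a BFB string must be nonempty")
  if (length(seg) != length(dir)) stop("seg and dir lengths differ")
  if (anyNA(seg) || anyNA(dir) || any(seg < 1L) || !all(dir %in% c(-1L, 1L)))
    stop("invalid segment indices or orientations")
  if (seg[1L] != 1L || dir[1L] != 1L)
    stop("a BFB string must start with '1+' (centromeric anchor)")
  used <- sort(unique(seg))
  if (!identical(used, seq_len(max(seg))))
    stop("segment indices used must form a prefix {1..k}")
  structure(list(seg = seg, dir = dir), class = "bfb_string")
}

#' @param x text encoding such as `"1+2+3+3-2-"`.
#' @rdname bfb_string
#' @export
parse_bfb <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("[0-9]+[+-]", x)[[1L]]
  toks <- regmatches(x, gregexpr("[0-9]+[+-]", x))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(x) || length(toks) == 0L)
    stop("cannot parse BFB string encoding: ", x)
  seg <- as.integer(sub("[+-]$", "", toks))
  dir <- ifelse(endsWith(toks, "+"), 1L, -1L)
  bfb_string(seg, dir)
}

#' @param ... unused.
#' @rdname bfb_string
#' @export
format.bfb_string <- function(x, ...) {
  paste0(x$seg, ifelse(x$dir > 0L, "+", "-"), collapse = "")
}

#' @export
print.bfb_string <- function(x, ...) {
  cat("<bfb_string> ", format(x), "  (", length(x$seg), " elements)\n", sep = "")
  invisible(x)
}

#' @export
length.bfb_string <- function(x) length(x$seg)

# mirror image: reverse element order and flip every orientation
inv_bfb <- function(s) {
  structure(list(seg = rev(s$seg), dir = rev(-s$dir)), class = "bfb_string")
}

as_bfb <- function(s) {
  if (inherits(s, "bfb_string")) s else parse_bfb(s)
}

#' Apply one breakage-fusion-bridge cycle
#'
#' One BFB cycle fuses the broken arm to its sister chromatid, forming the
#' dicentric `s . inv(s)`, and the anaphase bridge re-breaks, retaining a
#' prefix.  `apply_cycle()` returns the prefix of length `break_len` of
#' `s . inv(s)`, where `inv` reverses element order and flips every
#' orientation.  `break_len <= length(s)` models a pure loss (the break falls
#' before the fusion point); larger values retain part of the inverted copy
#' and create a foldback.
#'
#' @param s a [bfb_string] (or its text encoding).
#' @param break_len integer in `[1, 2 * length(s)]`.
#' @return The resulting [bfb_string].
#' @examples
#' format(apply_cycle("1+2+3+", 5))    # "1+2+3+3-2-"
#' format(apply_cycle("1+", 2))        # "1+1-"
#' @export
apply_cycle <- function(s, break_len) {
  s <- as_bfb(s)
  n <- length(s$seg)
  break_len <- as.integer(break_len)
  if (length(break_len) != 1L || is.na(break_len) ||
      break_len < 1L || break_len > 2L * n)
    stop("break_len must be in [1, ", 2L * n, "]")
  m <- inv_bfb(s)
  seg <- c(s$seg, m$seg)[seq_len(break_len)]
  dir <- c(s$dir, m$dir)[seq_len(break_len)]
  structure(list(seg = seg, dir = dir), class = "bfb_string")
}

#' Copy-number vector induced by a BFB string
#'
#' `C[i]` is the number of occurrences of segment `i` in either orientation;
#' mapped back to the reference this is the copy number of segment `i`.
#'
#' @inheritParams apply_cycle
#' @param n number of reference segments on the arm (>= max index used).
#' @return Integer vector of length `n`.
#' @examples
#' count_vector("1+2+3+3-2-2+2-2+3+3-2-", 4)  # 1 6 4 0
#' @export
count_vector <- function(s, n) {
  s <- as_bfb(s)
  n <- as.integer(n)
  if (n < max(s$seg)) stop("n is smaller than the largest segment index used")
  tabulate(s$seg, nbins = n)
}

#' Foldback vectors induced by a BFB string
#'
#' A right-foldback at segment `i` is an adjacency `(i,+)(i,-)`: the copy runs
#' into its own inversion at its telomeric end.  A left-foldback is the mirror
#' adjacency `(i,-)(i,+)`.  No other adjacency contributes.
#'
#' @inheritParams count_vector
#' @return `list(L = , R = )`, integer vectors of length `n`.
#' @examples
#' foldback_vectors("1+2+3+3-2-2+2-2+3+3-2-", 4)
#' @export
foldback_vectors <- function(s, n) {
  s <- as_bfb(s)
  n <- as.integer(n)
  if (n < max(s$seg)) stop("n is smaller than the largest segment index used")
  L <- integer(n); R <- integer(n)
  k <- length(s$seg)
  if (k > 1L) {
    a <- seq_len(k - 1L)
    same <- s$seg[a] == s$seg[a + 1L]
    right <- same & s$dir[a] == 1L & s$dir[a + 1L] == -1L
    left  <- same & s$dir[a] == -1L & s$dir[a + 1L] == 1L
    if (any(right)) R <- tabulate(s$seg[a][right], nbins = n)
    if (any(left))  L <- tabulate(s$seg[a][left], nbins = n)
  }
  list(L = L, R = R)
}

#' Decide whether a string is obtainable by BFB cycles
#'
#' Not every structure with abundant foldbacks and ladder-like amplification
#' can be produced by BFB cycles.  A string is a BFB string iff it can be
#' derived from some initial reference prefix `1+2+...k+` by zero or more
#' [apply_cycle()] steps.  Because a cycle with `break_len <= length(s)`
#' simply takes a prefix, the reachable set is prefix-closed and every member
#' has a growth-only derivation; the decision reduces to repeatedly stripping
#' a terminal fold.  `is_bfb_string()` runs that reduction as a dynamic
#' program over prefixes (prefix `b` is reachable iff it is a reference
#' prefix, or some `m < b` with `m >= ceiling(b/2)` has the suffix
#' `t[(m+1)..b]` equal to the mirror of `t[(2m-b+1)..m]` and prefix `m`
#' reachable).
#'
#' @inheritParams apply_cycle
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_bfb_string("1+2+3+3-2-2+2-2+3+3-2-")       # TRUE
#' is_bfb_string("1+2+2-2+2-2+2-3-3+3-3+")       # FALSE
#' @export
is_bfb_string <- function(s) {
  s <- as_bfb(s)
  seg <- s$seg; dir <- s$dir
  b <- length(seg)
  # reference prefixes: positions where seg == 1..m, dir all +
  ref <- cumsum(seg == seq_len(b) & dir == 1L) == seq_len(b)
  reach <- logical(b)
  for (m in seq_len(b)) {
    if (ref[m]) { reach[m] <- TRUE; next }
    if (m < 2L) next
    for (p in seq.int(ceiling(m / 2), m - 1L)) {
      if (!reach[p]) next
      j <- seq_len(m - p)
      if (all(seg[p + j] == seg[p + 1L - j]) &&
          all(dir[p + j] == -dir[p + 1L - j])) {
        reach[m] <- TRUE
        break
      }
    }
  }
  reach[b]
}
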