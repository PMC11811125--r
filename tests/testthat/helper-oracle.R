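# Independent brute-force oracle: breadth-first closure of apply_cycle()
# growth moves from every reference prefix, bounded by a maximum string
# length (shrinking cycles only produce prefixes, so the reachable set is
# the prefix closure of the growth closure).

bfs_reachable <- function(n_seg, max_len, cmax = NULL) {
  seen <- new.env(parent = emptyenv())
  queue <- list()
  for (k in seq_len(n_seg)) {
    if (!is.null(cmax) && any(cmax[seq_len(k)] < 1L)) break
    s <- bfb_string(seq_len(k), rep(1L, k))
    key <- format(s)
    if (is.null(seen[[key]])) { seen[[key]] <- TRUE; queue[[length(queue) + 1L]] <- s }
  }
  i <- 1L
  while (i <= length(queue)) {
    s <- queue[[i]]; i <- i + 1L
    len <- length(s)
    for (b in (len + 1L):(2L * len)) {
      if (b > max_len) break
      child <- apply_cycle(s, b)
      if (!is.null(cmax)) {
        cv <- count_vector(child, length(cmax))
        if (any(cv > cmax)) next
      }
      key <- format(child)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        queue[[length(queue) + 1L]] <- child
      }
    }
  }
  queue
}

# prefix closure of a set of strings, as encodings
prefix_closure <- function(strings) {
  out <- new.env(parent = emptyenv())
  for (s in strings) {
    for (m in seq_along(s$seg)) {
      key <- format(bfb_string(s$seg[seq_len(m)], s$dir[seq_len(m)]))
      out[[key]] <- TRUE
    }
  }
  ls(out)
}

# tiny deterministic label track
toy_track <- function(cn_runs, run_len = 10L, spacing = 5000, z1 = 10,
                      chrom = "chr1") {
  cn <- rep(cn_runs, each = run_len)
  pos <- seq_along(cn) * spacing
  label_track(chrom, pos, coverage = z1 * cn, cn = cn)
}
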