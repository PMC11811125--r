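# Direct construction of a BFB string realizing a target (C, L, R).
#
# Every BFB string t yields the even palindrome t* = t . inv(t) (one full
# cycle), whose counts are doubled and whose centre adjacency is the fold at
# t's last element.  In t*, the occurrences of segments >= l form maximal
# blocks; each block is a palindrome built from "hairpin units"
# (l,+) gap (l,-), where a gap is either empty (a right fold at l) or one
# complete (l+1)-block, and consecutive units join by left folds at l.
# Counting segment-occurrence ends gives, for t* with centre fold at (j, o)
# and per-layer unit counts U_l = C_l:
#
#     #blocks at layer l+1:  b[l+1] = C_l - 2 R_l - [centre == (l,+)]
#     #blocks at layer l:    b[l]   = C_l - 2 L_l - [centre == (l,-)]
#
# with b[1] = 1 (the root) and b[k+1] = 0.  Two spines constrain the
# arrangement: t starts with the reference prefix 1+2+...k+, so the first
# gap of each layer's start block holds the next layer's start block (an
# empty gap at the top layer); and the centre of t* runs down a centre
# spine ending in the fold (j, o).  Within those constraints each layer's
# gap words must be palindromes, which couples the layers: a block content
# occurring an odd number of times can only sit at the middle of a word one
# layer down, so the arrangement keeps the produced content multiset as
# even as possible and rations odd leftovers by the capacity of the layer
# below.  Every candidate is verified against the target vectors and
# is_bfb_string() before being returned, so the constructor is sound by
# checking; the bounded search of enumerate_architectures() remains as a
# fallback and the source of near-matches.

# --- one layer's arrangement -------------------------------------------------
#
# types: list(content = signed integer vector (integer(0) = empty gap),
#             count =) -- the gap items of this layer, including the start
#   block of the layer above (its type index in `start_type`) but not the
#   centre block (carried separately, placed via "ITEM").
# B: number of words (blocks) to build.
# center_kind: NA, "item", "empty", "none", "single" (see construct).
# rot: retry knob.
#
# Words are represented as list(left = type indices (one side of the
# palindrome), center = type index or NA, fixed_center = "E"/"ITEM"/NULL,
# start = type index or NA).  Word 1 is the start word, word B the centre
# word when a centre is constrained.

arrange_layer <- function(types, B, start_type = NA_integer_,
                          center_kind = NA_character_,
                          need_twin = FALSE, rot = 0L,
                          allow_lone = TRUE, upgrade = FALSE) {
  counts0 <- vapply(types, `[[`, 0L, "count")
  empty_word <- function() list(left = integer(0), center = NA_integer_,
                                fixed_center = NULL, start = NA_integer_)
  ci <- if (center_kind %in% c("item", "empty", "none")) B else NA_integer_
  if (identical(center_kind, "single")) ci <- 1L

  # --- B == 1: the single word takes everything -----------------------------
  if (B == 1L) {
    w <- empty_word()
    counts <- counts0
    if (identical(center_kind, "single")) {
      w$fixed_center <- "ITEM"
      if (sum(counts) > 0L) return(NULL)    # nothing else fits a 1-unit word
      return(list(w))
    }
    if (identical(center_kind, "empty")) {
      e <- which(vapply(types, function(t) length(t$content) == 0L, TRUE))
      if (!length(e) || counts[e[1L]] < 1L) return(NULL)
      counts[e[1L]] <- counts[e[1L]] - 1L
      w$fixed_center <- "E"
    } else if (identical(center_kind, "item")) {
      w$fixed_center <- "ITEM"
    }
    odd <- which(counts %% 2L != 0L)
    if (length(odd) > 1L) return(NULL)
    if (length(odd) == 1L) {
      if (!is.null(w$fixed_center) || identical(center_kind, "none"))
        return(NULL)
      w$center <- odd
      counts[odd] <- counts[odd] - 1L
    }
    # remaining counts even; the first item of the word must be the start
    halves <- unlist(mapply(function(t, m) rep.int(t, m %/% 2L),
                            seq_along(counts), counts, SIMPLIFY = FALSE),
                     use.names = FALSE)
    if (is.null(halves)) halves <- integer(0)
    if (!is.na(start_type)) {
      if (length(halves)) {
        if (counts[start_type] < 2L) return(NULL)
        halves <- c(start_type, halves[-match(start_type, halves)])
      } else {
        # the word is its centre alone; it must be compatible with the start
        ctr_ok <- (!is.na(w$center) && w$center == start_type) ||
          (identical(w$fixed_center, "E") &&
             length(types[[start_type]]$content) == 0L) ||
          identical(w$fixed_center, "ITEM")
        if (!ctr_ok) return(NULL)
      }
    }
    w$left <- halves
    if (identical(center_kind, "none") && length(w$left) == 0L) return(NULL)
    if (length(w$left) == 0L && is.na(w$center) && is.null(w$fixed_center))
      return(NULL)
    return(list(w))
  }

  # --- B >= 2 ---------------------------------------------------------------
  # The contents of the start word (consumed as the next layer's start) and
  # of the centre-spine word (carried separately) never enter the pool one
  # layer down, so they are parity-exempt; every other content must appear
  # an even number of times, except that one lone word may emit an odd
  # content for the next layer to absorb at its own start word's middle.
  # Start-word configurations: "pair" puts two start instances at the ends
  # and frees the middle for one odd type, "single" is the minimal [start],
  # "twin" adds an identical copy of the minimal word so the layer below can
  # take the start content twice.
  configs <- if (need_twin && !allow_lone) "twin" else
    if (need_twin) c("twin", "pair", "single") else
    if (rot %% 2L == 0L) c("pair", "single", "twin") else
      c("single", "pair", "twin")
  if (identical(center_kind, "single")) configs <- "coincide"
  for (cfg in configs) {
    res <- arrange_b2(types, counts0, B, ci, start_type, center_kind,
                      cfg, rot, empty_word, allow_lone, upgrade)
    if (!is.null(res)) return(res)
  }
  NULL
}

arrange_b2 <- function(types, counts, B, ci, start_type, center_kind,
                       cfg, rot, empty_word, allow_lone = TRUE,
                       upgrade = FALSE) {
  words <- replicate(B, empty_word(), simplify = FALSE)
  twin <- NA_integer_
  word1_open <- FALSE                 # word 1 may absorb odd centre / tokens
  if (identical(cfg, "coincide")) {
    words[[1L]]$fixed_center <- "ITEM"
  } else {
    if (is.na(start_type)) return(NULL)
    need <- switch(cfg, pair = 2L, single = 1L, twin = 2L)
    if (counts[start_type] < need) return(NULL)
    counts[start_type] <- counts[start_type] - need
    if (cfg == "pair") {
      words[[1L]]$start <- start_type
      word1_open <- TRUE
    } else {
      words[[1L]]$center <- start_type
    }
  }
  # centre word
  if (identical(center_kind, "empty")) {
    e <- which(vapply(types, function(t) length(t$content) == 0L, TRUE))
    if (!length(e) || counts[e[1L]] < 1L) return(NULL)
    counts[e[1L]] <- counts[e[1L]] - 1L
    words[[ci]]$fixed_center <- "E"
  } else if (identical(center_kind, "item")) {
    words[[ci]]$fixed_center <- "ITEM"
  }
  fixed <- unique(c(1L, if (!is.na(ci)) ci))
  off <- setdiff(seq_len(B), fixed)
  if (identical(cfg, "twin")) {
    if (!length(off)) return(NULL)
    twin <- off[length(off)]
    words[[twin]]$center <- start_type
    off <- setdiff(off, twin)
  }
  # odd types: one may sit at word 1's free middle (pair form); at most one
  # more becomes a lone word whose odd content the next layer absorbs
  odd_types <- which(counts %% 2L == 1L)
  if (rot > 1L && length(odd_types) > 1L) {
    r <- (rot %/% 2L) %% length(odd_types)
    if (r > 0L) odd_types <- c(odd_types[-seq_len(r)], odd_types[seq_len(r)])
  }
  if (word1_open && length(odd_types)) {
    words[[1L]]$center <- odd_types[1L]
    counts[odd_types[1L]] <- counts[odd_types[1L]] - 1L
    odd_types <- odd_types[-1L]
    word1_open <- FALSE               # middle now taken; left still open
  }
  if (length(odd_types) > min(if (allow_lone) 1L else 0L, length(off)))
    return(NULL)
  lone <- off[seq_along(odd_types)]
  for (i in seq_along(odd_types)) {
    words[[lone[i]]]$center <- odd_types[i]
    counts[odd_types[i]] <- counts[odd_types[i]] - 1L
  }
  rest <- setdiff(off, lone)
  # remaining counts all even; fill remaining off words in identical pairs
  groups <- list()
  gtype <- integer(0)                   # base type of each group (0: start)
  if (!is.na(twin)) { groups[[1L]] <- c(1L, twin); gtype <- 0L }
  while (length(rest) >= 2L) {
    cand <- which(counts >= 2L)
    if (!length(cand)) return(NULL)
    t <- cand[order(-counts[cand])][1L]
    counts[t] <- counts[t] - 2L
    words[[rest[1L]]]$center <- t
    words[[rest[2L]]]$center <- t
    groups[[length(groups) + 1L]] <- rest[1:2]
    gtype <- c(gtype, t)
    rest <- rest[-(1:2)]
  }
  if (length(rest) == 1L) {
    # a leftover word with unique content: costs the lone slot
    if (!allow_lone) return(NULL)
    cand <- which(counts >= 2L)
    if (!length(cand)) return(NULL)
    t <- cand[order(-counts[cand])][1L]
    counts[t] <- counts[t] - 2L
    words[[rest[1L]]]$left <- t      # content [t, t]; odd content
    # this odd content consumes the lone slot if still free
    if (length(odd_types) >= 1L || length(lone) >= 1L) return(NULL)
    lone <- rest[1L]
    rest <- integer(0)
  }
  # leftover pairs ("tokens"): exempt sinks (centre-spine word, word 1 in
  # pair form, the "none" centre word) and the lone word absorb any number;
  # groups absorb tokens two at a time
  sink <- c(if (!is.na(ci) && !identical(center_kind, "none") && ci != 1L) ci,
            if (!is.na(words[[1L]]$start)) 1L,
            if (identical(center_kind, "none")) ci,
            lone)
  if (identical(center_kind, "none")) {
    cand <- which(counts >= 2L)
    if (!length(cand)) return(NULL)
    t0 <- cand[order(-counts[cand])][1L]
    counts[t0] <- counts[t0] - 2L
    words[[ci]]$left <- c(words[[ci]]$left, t0)
  }
  # without an odd-capable sink, each type needs an even token count; two
  # repairs: upgrading a same-type group from centre-form [t] to left-form
  # [t,t] absorbs one token, and retyping a base group flips the token
  # parity of two types at once
  if (!length(sink)) {
    if (upgrade) for (t in which((counts %/% 2L) %% 2L == 1L)) {
      gi <- which(gtype == t)
      if (length(gi) && counts[t] >= 2L) {
        g <- groups[[gi[1L]]]
        for (wi in g) {
          words[[wi]]$center <- NA_integer_
          words[[wi]]$left <- c(words[[wi]]$left, t)
        }
        counts[t] <- counts[t] - 2L
      }
    }
    repeat {
      stray <- which((counts %/% 2L) %% 2L == 1L)
      if (length(stray) < 2L) break
      t1 <- stray[1L]; t2 <- stray[2L]
      gi2 <- which(gtype == t2)
      gi1 <- which(gtype == t1)
      if (length(gi2) && counts[t1] >= 2L) {
        g <- groups[[gi2[1L]]]
        words[[g[1L]]]$center <- t1; words[[g[2L]]]$center <- t1
        gtype[gi2[1L]] <- t1
        counts[t1] <- counts[t1] - 2L; counts[t2] <- counts[t2] + 2L
      } else if (length(gi1) && counts[t2] >= 2L) {
        g <- groups[[gi1[1L]]]
        words[[g[1L]]]$center <- t2; words[[g[2L]]]$center <- t2
        gtype[gi1[1L]] <- t2
        counts[t2] <- counts[t2] - 2L; counts[t1] <- counts[t1] + 2L
      } else break
    }
  }
  grp_ok <- which(gtype != 0L)          # groups that may absorb dumps
  for (t in seq_along(counts)) {
    m <- counts[t] %/% 2L
    if (length(sink)) {
      while (m >= 1L) {
        ft <- sink[1L + (m + t + rot) %% length(sink)]
        words[[ft]]$left <- c(words[[ft]]$left, t)
        m <- m - 1L
      }
    }
    while (m >= 2L && length(grp_ok)) {
      g <- groups[[grp_ok[1L + (m + rot) %% length(grp_ok)]]]
      words[[g[1L]]]$left <- c(words[[g[1L]]]$left, t)
      words[[g[2L]]]$left <- c(words[[g[2L]]]$left, t)
      m <- m - 2L
    }
    if (m > 0L) return(NULL)
  }
  if (identical(center_kind, "none")) {
    w <- words[[ci]]
    if (length(w$left) == 0L || !is.na(w$center) || !is.null(w$fixed_center))
      return(NULL)
  }
  for (w in words) {
    if (length(w$left) == 0L && is.na(w$center) && is.null(w$fixed_center) &&
        is.na(w$start)) return(NULL)
  }
  words
}

# assemble the signed-element content of one layer-l block from its word
word_content <- function(word, l, types, center_item = NULL,
                         ord_mode = 0L) {
  item <- function(t) {
    if (is.null(t)) return(integer(0))
    if (identical(t, "E")) return(integer(0))
    if (identical(t, "ITEM")) return(center_item)
    types[[t]]$content
  }
  unit <- function(g) c(l, g, -l)
  # deeper (longer) gap contents first: folds copy progressively shallower
  # suffixes, so a half-word that descends in depth reduces more readily
  left <- word$left
  if (length(left) > 1L) {
    depth <- vapply(left, function(t) length(types[[t]]$content), 0L)
    left <- if (ord_mode == 1L) left[order(depth)] else left[order(-depth)]
  }
  lefts <- c(if (!is.na(word$start)) list(unit(item(word$start))),
             lapply(left, function(t) unit(item(t))))
  center <- if (!is.null(word$fixed_center)) {
    list(unit(item(word$fixed_center)))
  } else if (!is.na(word$center)) {
    list(unit(item(word$center)))
  } else list()
  unlist(c(lefts, center, rev(lefts)))
}

# --- the constructor ---------------------------------------------------------

#' Construct a BFB string realizing target copy and foldback vectors
#'
#' Solves the inverse problem: given per-segment copy numbers `C` and
#' left/right foldback counts `L`, `R`, builds a BFB string whose induced
#' vectors equal the targets exactly, or returns `NULL` when no such string
#' is found.  Per-layer block-count equations reject most unrealizable
#' targets immediately, and every constructed string is verified against
#' [count_vector()], [foldback_vectors()] and [is_bfb_string()] before
#' being returned.
#'
#' @param C,L,R non-negative integer vectors of equal length (trailing
#'   zeros in `C` allowed).
#' @return A [bfb_string] or `NULL`.
#' @examples
#' s <- construct_architecture(c(1, 6, 4, 0), c(0, 2, 0, 0), c(0, 1, 2, 0))
#' format(s)
#' @export
construct_architecture <- function(C, L, R) {
  C <- as.integer(C); L <- as.integer(L); R <- as.integer(R)
  n <- length(C)
  stopifnot(length(L) == n, length(R) == n)
  if (any(C < 0) || any(L < 0) || any(R < 0)) return(NULL)
  k <- max(c(0L, which(C > 0)))
  if (k == 0L || any(C[seq_len(k)] == 0L)) return(NULL)
  if (k < n && (any(L[(k + 1L):n] > 0) || any(R[(k + 1L):n] > 0))) return(NULL)
  # a leading segment with one copy and no folds is a pure centromeric
  # anchor: it occurs exactly once, at the start, so the rest of the string
  # is itself a BFB architecture over the remaining segments
  if (k > 1L && C[1L] == 1L && L[1L] == 0L && R[1L] == 0L) {
    sub <- construct_architecture(C[2:n], L[2:n], R[2:n])
    if (is.null(sub)) return(NULL)
    return(bfb_string(c(1L, sub$seg + 1L), c(1L, sub$dir)))
  }
  Ck <- C[seq_len(k)]; Lk <- L[seq_len(k)]; Rk <- R[seq_len(k)]
  for (j in seq_len(k)) for (o in c(1L, -1L))
  for (strict in c(TRUE, FALSE)) for (upgrade in c(FALSE, TRUE))
  for (rot in 0:9) {
    res <- construct_with_center(Ck, Lk, Rk, j, o, rot, strict, upgrade)
    if (is.null(res)) next
    s <- bfb_string(abs(res), sign(res))
    if (identical(count_vector(s, n), C)) {
      fb <- foldback_vectors(s, n)
      if (identical(fb$L, L) && identical(fb$R, R) &&
          .is_bfb_cpp(s$seg, s$dir))
        return(s)
    }
  }
  NULL
}

construct_with_center <- function(C, L, R, j, o, rot = 0L, strict = TRUE,
                                  upgrade = FALSE) {
  k <- length(C)
  bR <- C - 2L * R - as.integer(seq_len(k) == j & o == 1L)   # b[l+1]
  bL <- C - 2L * L - as.integer(seq_len(k) == j & o == -1L)  # b[l]
  if (bL[1L] != 1L) return(NULL)
  if (k > 1L && any(bL[2:k] != bR[1:(k - 1L)])) return(NULL)
  if (bR[k] != 0L) return(NULL)
  b <- c(bL, 0L)
  if (any(b[seq_len(k)] < 1L)) return(NULL)
  off_above <- list()
  start_above <- NULL
  center_above <- NULL
  coincide_above <- FALSE
  for (l in k:1L) {
    E <- 2L * R[l] + as.integer(l == j && o == 1L)
    types <- list()
    if (E > 0L) types <- list(list(content = integer(0), count = E))
    if (length(off_above)) {
      keys <- vapply(off_above, paste, "", collapse = ",")
      for (key in unique(keys)) {
        i <- which(keys == key)[1L]
        types <- c(types, list(list(content = off_above[[i]],
                                    count = sum(keys == key))))
      }
    }
    center_kind <- NA_character_
    if (l <= j) {
      center_kind <- if (l < j) { if (coincide_above) "single" else "item" }
      else if (o == 1L) "empty" else "none"
    }
    start_type <- NA_integer_
    if (!identical(center_kind, "single")) {
      start_content <- if (l == k) integer(0) else start_above
      key0 <- paste(start_content, collapse = ",")
      idx <- which(vapply(types, function(t)
        paste(t$content, collapse = ",") == key0, TRUE))
      if (!length(idx)) {
        types <- c(types, list(list(content = start_content, count = 0L)))
        idx <- length(types)
      }
      start_type <- idx[1L]
      if (l < k) types[[start_type]]$count <- types[[start_type]]$count + 1L
    }
    words <- NULL
    tws <- if (strict) (l >= 2L && C[1L] >= 2L) else
      unique(c(l >= 2L && C[1L] >= 2L, FALSE))
    for (tw in tws) {
      words <- arrange_layer(types, b[l], start_type = start_type,
                             center_kind = center_kind,
                             need_twin = tw, rot = rot,
                             allow_lone = !strict, upgrade = upgrade)
      if (!is.null(words)) break
    }
    if (is.null(words)) return(NULL)
    contents <- lapply(words, word_content, l = l, types = types,
                       center_item = center_above,
                       ord_mode = as.integer(rot >= 8L))
    if (l <= j) {
      ci <- if (identical(center_kind, "single") || b[l] == 1L) 1L
            else length(contents)
      center_next <- contents[[ci]]
      start_next <- contents[[1L]]
      off <- contents[-unique(c(1L, ci))]
      coincide_next <- (ci == 1L)
    } else {
      center_next <- NULL
      start_next <- contents[[1L]]
      off <- contents[-1L]
      coincide_next <- FALSE
    }
    off_above <- off
    start_above <- start_next
    center_above <- center_next
    coincide_above <- coincide_next
  }
  root <- if (!is.null(center_above)) center_above else start_above
  len <- length(root)
  if (len %% 2L != 0L) return(NULL)
  root[seq_len(len %/% 2L)]
}
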