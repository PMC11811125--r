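---
title: "Detecting breakage-fusion-bridge amplicons from label-level evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting breakage-fusion-bridge amplicons from label-level evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfbscope)
```

## The model

A breakage-fusion-bridge (BFB) cycle fuses the sister chromatids of a broken
chromosome arm, forms a dicentric bridge at anaphase, and re-breaks.  Writing
the arm as consecutive reference segments `1..k` (centromere to telomere),
one cycle maps an architecture string `s` to a prefix of `s·inv(s)`, where
`inv` reverses the element order and flips every orientation
(`apply_cycle()`).  Iterating from the reference prefix `1+2+...k+`
generates the *BFB language*; each string induces a copy-number vector `C`
(occurrences per segment), right-foldback counts `R` (adjacencies
`(i,+)(i,-)`) and left-foldback counts `L` (`(i,-)(i,+)`).  Ladder-like
amplification with abundant foldbacks is *suggestive* of BFB, but not every
such profile lies in the BFB language, and the package's central question is
whether a candidate amplicon's observed profile does.

Observed data is the label-level abstraction of an optical-genome-mapping
workflow: for each label, raw molecule coverage `V`, called copy number `N`,
and the molecule sets supporting left and right foldback junctions.  The
scale factor `Z₁ = ΣV / ΣN` converts molecule counts to copy-number units,
so a segment's observed foldback copy numbers are the sizes of the unions of
supporting molecule sets over its labels divided by `Z₁` (the union, not the
sum, deduplicates molecules seen at several labels).

A candidate architecture `(C, L, R)` is scored against a latent segment
profile `(C°, L°, R°)` by

\[
\mathrm{score} \;=\; \frac{1}{n^{c}}\Big[\;
  \sum_i \frac{|C^\circ_i - C_i|}{\max(C_i, 1)}
  + \alpha\,\lVert (L^\circ,R^\circ) - (L,R)\rVert_2
  + P_1 F
  \;+\; \sum_{s=1}^{n}\frac{\sum_{i\in s}|N_i - C^\circ_s|}{m_s}\Big],
\]

where `F` counts segments whose observed foldback has no predicted
counterpart (a predicted-but-unobserved foldback is *not* penalised beyond
the Euclidean term, because foldback detection is lossy in real data), and
`m_s` is the number of labels in segment `s`.  Scores below the threshold
1.8 classify an amplicon BFB-positive; amplicons removed by the candidate
filters report the sentinel 4, which is never compared against the
threshold.  The copy term divides by `max(C_i, 1)` so that architectures
with deleted segments (the lost telomeric tail has `C = 0`) remain
scoreable.

## Parameters

All tunables live in `bfb_params()`, each with its published default:
`alpha = 7` (weight of the foldback Euclidean term), `p1 = 1` (penalty per
missing-foldback segment), `c = 0.9` (segment-count exponent),
`threshold = 1.8`, sentinel 4; candidate filters `cn_min = 3` (strict),
`fb_excess = 1.1` over the genome-wide mean per-label foldback support,
linkage `link_dist_bp = 1.5e6` or `link_cn = 7`; CBS weights saturate at
`weight_cap_bp = 1e4` and smoothing merges monotone middle segments shorter
than `smooth_frac = 0.07` of the candidate-region length.  Thresholds
appear once, here, and flow through the package.

Two parameters are this package's own: `pad_bp` (default 3e5) extends a
candidate region with flanking context before fitting, so the architecture
can use the centromeric CN-1 anchor and the telomeric-loss signal — the
worked four-segment example `[1, 6, 4, 0]` uses both; and
`orientation = "auto"` fits the arm in both directions when the flanks do
not disambiguate which end faces the centromere, keeping the lower score
(an arm whose telomeric side collapses to copy number ~0 is oriented
directly, since a leading zero is impossible in a BFB vector).

## Segmentation

`N` is segmented by weighted circular binary segmentation: each label's
weight is its preceding inter-label gap divided by 10 kbp, capped at 1 (the
first label uses its following gap — the rule's source is silent on this
label).  Splits are accepted by a permutation test on the maximal weighted
arc statistic (`cbs_alpha = 0.01`, `cbs_nperm = 200`, sequential early
stopping); on noiseless piecewise-constant input the recovered breakpoints
are exact, which is the property that calibrates these conventional
defaults.  The 7% smoothing rule is measured against the *candidate
region's* genomic length, not the padded fitting window — measured against
the padded window it deletes genuine ~100 kbp segments.  Because a
permutation test can leave a short interior run unsplit, initialisation
ends with a greedy refinement pass that applies two-means cuts while they
reduce a segment's mean absolute deviation by at least 0.3 copies; spurious
extra cuts are harmless because the sampler can merge them and the score
normalises by the number of *distinct copy-number runs* rather than raw
segments (splitting a constant stretch must not inflate `n`).

## Architecture enumeration

Every BFB string has a growth-only derivation, along which `(C, L, R)` are
componentwise monotone (each cycle appends the mirrored suffix plus exactly
one new fold).  `enumerate_architectures()` therefore searches growth
derivations depth-first under componentwise bounds, which is exhaustive
within the bounds given budget; with a node budget it returns the best
candidates found and a truncation flag, falling back to randomized-restart
passes with shuffled move orders, and to an approximate phase with relaxed
copy bounds when no exact match exists.  Candidates are deduplicated by
their `(C, L, R)` class and ranked by ascending relative copy discrepancy
with a lexicographic tie-break.

The searches are complemented by `construct_architecture()`, a direct
solver for the inverse problem: doubling a BFB string `t` to the palindrome
`t·inv(t)` makes every maximal block of segments `≥ l` a palindrome of
"hairpin units" `(l,+) gap (l,-)`, whose gaps are empty (right folds) or
single blocks of the layer above, joined by left folds.  Counting ends
yields per-layer block-count equations in `(C, L, R)` and the fold at the
string's last element; when they are consistent, the blocks are arranged
into palindromic gap words constrained by two spines (the reference prefix
at the start, the centre fold of the doubled string) and parity discipline
(contents must pair up except at word middles).  The arrangement heuristics
are not complete, so every constructed string is verified against
`count_vector()`, `foldback_vectors()` and `is_bfb_string()` before use —
the constructor is sound by checking, and resolves the large majority of
simulated ground-truth classes directly, in milliseconds.  `is_bfb_string()`
itself is a dynamic program over prefixes that strips terminal folds, and
is certified in the tests against a brute-force breadth-first oracle over
`apply_cycle()`.

## Gibbs refinement

The latent profile is refined by Metropolis-within-Gibbs against
`exp(-Δ_model - Δ_data)`: resampling one segment's `(C°, L°, R°)` on
discrete grids *anchored at the data-derived values* (probability 0.45) —
the data term does not constrain `L°` and `R°`, so proposals centred on the
current state would let the foldback profile drift freely toward any
candidate, erasing the very mismatch that separates negatives from
positives; shifting one segment boundary by up to three labels (0.15),
which repairs off-by-a-label boundaries that drag a junction into the wrong
segment; merging adjacent segments (0.2); or splitting a segment (0.2),
half the time at the segment's best two-means cut.  Dimension moves are first evaluated with
candidates *transformed* across the segmentation change (splitting a
reference segment duplicates its copy number; each copy spans both halves)
and re-enumerated only when accepted, with per-call caching — re-running
the full search on every proposal would dominate the runtime.  Dimension
moves use deterministic data-driven proposal values without a
reversible-jump correction: the procedure is used as a stochastic
minimiser, the minimum-score configuration visited is returned, and the
initial configuration is always visited, so the returned score never
exceeds the deterministic initialisation's.  The default schedule is 1200
iterations with early exit at score zero or after a 400-iteration plateau,
and the best latent found receives one final full-budget enumeration (the
in-sampler searches are deliberately cheap and exact-only); all draws come
from R's seeded stream, so runs are exactly reproducible.

## What the simulator emulates

`simulate_bfb()` draws random break lengths through `apply_cycle()`; with a
target mean copy number it steers break lengths so the total copy count
lands on target, redrawing derivations whose largest per-segment copy
number escapes the design neighbourhood (cap `max(100, 1.6×target)`) so
that simulated ladders stay in the studied 5–80 copy-number regime.  The
lost telomeric tail renders at copy number 0 — the physical aftermath of a
BFB — and a 500 kbp centromeric flank at copy number 1.  Tier `"simple"`
has no fold-region deletions or indels; `"intermediate"` adds exponential
(mean 2 kbp) deletions at fold junctions, which separate the aligned
foldback ends and nick the local copy number; `"complex"` adds internal
indels.  Negatives place amplified segments on an *intact* background:
ecDNA-like structures amplify 1–10 segments to high copy number with
optional duplication-inversions (the only source of genuine foldbacks);
chromothripsis-like structures shatter a region, retain pieces at moderate
copy number and emit foldback-like junctions at a subset of boundaries.

`render_observed()` places labels with exponential spacing (mean 5 kbp),
draws coverage `V ~ Poisson(Z₁ · copy number)` and supporting molecules
`Binomial(Z₁ · multiplicity, 1 - dropout)` per junction.  The default
`noise = "called"` mode reports `N` the way an upstream copy-number caller
would — piecewise exact per segment with 0.1-copy per-label wobble (an
optional per-segment relative bias is off by default) — because the
detection method consumes *called* copy numbers, whose error structure is
segmental rather than per-label shot noise; the `"poisson"` mode
(`N = V/Z₁`) is kept for studying the raw-coverage regime, and `"gradual"`
boundaries convolve the profile with a running-mean ramp the way
segmentation boundaries blur in real data.  Fold-region deletions separate
the aligned foldback junction ends but do not dent the copy-number track,
which is reported at segment resolution upstream.  What passing simulated
tests do *not* establish: performance under assembly/alignment artefacts,
reference-mappability gaps, tumour heterogeneity or subclonal mixtures —
none of which the renderer emulates.

## Design choices in degenerate territory

* A single amplified segment carrying both left and right foldbacks with
  intact flanks is *information-theoretically indistinguishable* from an
  ecDNA duplication-inversion at this abstraction, and is filtered with the
  sentinel score.  A genuine one-segment BFB ladder differs only through
  the telomeric-loss signal (adjacent copy number ~0), so the filter fires
  only when no loss evidence is adjacent — this is what keeps the
  noiseless-limit recall of simulated positives at 1 while still removing
  the ecDNA mimics.
* The score's `n` counts distinct copy-number runs of the latent profile;
  raw segment counts would let degenerate splits of constant stretches
  shrink any score by inflating `n^c`.
* Calibration (`calibrate_params()`) re-weights stored per-case score
  components over the `(P₁, α, c)` grid rather than re-running the full
  pipeline per grid point; the candidate chosen per case is held fixed,
  which is the approximation that makes the grid search affordable.
* When no candidate architecture is admissible the reported score is the
  sentinel, flat in `n` — an `n`-dependent fallback would reward the
  sampler for degenerate merging.
* Enumeration inside the sampler is exact-only with a small budget; the
  initial enumeration gets the full budget including the approximate
  phase.  Exact-phase completeness matters because a BFB-positive call at
  score 0 requires the candidate's foldback vectors to match the observed
  ones exactly.

## Problem sizes

The test suite exercises the brute-force oracle over all count vectors with
up to 4 segments and entries ≤ 6, string-level membership exhaustively over
2 segments up to length 6, noiseless-limit recovery over 50 seeded
positives, and a 100 + 100 simulated benchmark (positives with 1–7 segments
and mean copy numbers 5–80 across the three tiers; negatives mixing
ecDNA-like and chromothripsis-like structures 5:1) with an F1 sweep over
score thresholds, the scale at which the package's distributional claims
are stated.

## Known limitations

The inverse constructor is incomplete for a small minority of foldback
classes (intricate parity interactions between palindrome layers); the
bounded searches recover some of these, and the remainder surface as
inflated scores on otherwise valid BFB profiles — visible in the tests as
occasional simulated positives scoring above zero.  Translocation bridges,
BFB followed by chromothripsis, duplicated-translocated BFB arms and ecDNA
structure reconstruction are out of scope.  Reported scores on real
cell-line amplicons depend on upstream assembly and SV calling that the
package does not model.
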