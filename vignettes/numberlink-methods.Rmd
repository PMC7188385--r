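---
title: "Numberlink puzzles as a cognitive-motor assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numberlink puzzles as a cognitive-motor assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numberlink)
```

## The instrument

A Numberlink puzzle is a `width x height` grid in which labelled dot pairs
must be joined by continuous orthogonal paths that never cross, never pass
through a foreign dot, each traverse at least one empty cell (path length
>= 3 cells), and jointly cover every cell of the board. Solved on a
touchscreen, each level yields two text streams: time-stamped touch events
(`down/move/up/hint/solved` with pixel coordinates) and board-state
snapshots (one record per cell-state change). From these the package
computes, per level:

| measure | definition | units |
|---|---|---|
| TST | time from first touch to the solved event | s |
| MET | sum of drag-move (down-to-release) durations | s |
| MPT | TST − MET: touch-free thinking time | s |
| false moves | drawn paths absent from the final solution, or deleted/overwritten before it | count |
| excess moves | total moves − dot pairs (hint-completed pairs excluded) | count |
| MVE | mean over sub-paths of arc length / duration | px/s |
| MDC | along-axis velocity sign reversals within sub-paths | count |

Sub-paths are the axis-aligned portions of a drag delimited by the turns
detected with the Ramer–Douglas–Peucker (RDP) polyline simplification:
interior vertices retained at tolerance ε are the turns; a move with *n*
detected turns yields *n + 1* sub-paths, each assigned the axis of its
dominant displacement.

## Graded difficulty and parallel sets

Difficulty is governed by four board characteristics: size
(`width x height`), number of paths, total number of turns, and the mean
city-block distance between the dots of a pair. The graded space takes all
dimensions in 4..8 and both path and turn counts in
`[4, max(width, height)]`; `enumerate_level_space()` enumerates it
(25 board sizes; 15 square `(w, h, p)` families; 395 tuples in total by
direct summation of `(max(w, h) - 3)^2` over the boards). Two parallel
sets share all square families; each non-square board family appears in
both sets with opposite orientation, alternating along the path-count
index, so the sets have identical multisets of `(area, paths)`. Versions
restrict dimensions to `{4,5,6}` (short), `{4..7}` (medium) or `{4..8}`
(long) and shuffle presentation order seed-deterministically. A fixed
three-level practice block `(4,4,4,0), (4,4,4,4), (5,5,5,5)` precedes
assessment, and version assignment uses screening cut-offs (short when
MoCA < 23 **or** TMT-B > 120 s; long when MoCA > 28 **and** TMT-B < 120 s;
medium otherwise). The printed criteria in the source protocol are
non-exhaustive conjunctions; we resolve them with ordered precedence
short > medium > long, treating the short criteria as a disjunction, so
borderline participants receive the easier set.

## Puzzle generation

`generate_puzzle()` must return a *full-cover* reference solution with
exactly `n_paths` paths whose turn counts sum to exactly `n_turns`. A
natural first design — grow `n_paths` random walks by frontier expansion
and post-filter on the turn total — turns out to be unworkable: random
walk covers have turn totals far above the graded range (4..8 on boards up
to 8x8), so the post-filter essentially never accepts, and some nominal
tuples admit no cover at all. A path with *k* turns has *k + 1* alternating
segments and can cover at most `nH·w + nV·h − k` cells; summing this bound
over 4 paths sharing 4 turns caps coverage at 60 of the 64 cells of an
8x8 board, so `(8,8,4,4)` is infeasible outright.

The implemented generator is constructive instead:

1. build a serpentine Hamiltonian path (random orientation/reflections;
   turn total `2(min(w,h) − 1)`), then randomize it with *backbite* moves
   (reverse a suffix onto a neighbouring cell), which keep the path
   Hamiltonian while drifting the turn total;
2. once the turn total `T` lies in `[t, t + 2(p−1)]`, cut the path into
   `p` segments of at least 3 cells. A cut adjacent to a corner cell turns
   that corner into a segment endpoint and deletes its turn, so each cut
   removes 0, 1 or 2 turns; a small boolean dynamic program selects a
   random cut placement removing exactly `T − t` turns;
3. segment endpoints become the dot pairs; rejection sampling over
   Hamiltonian paths (capped by `max_attempts`) covers targets the current
   path cannot reach.

The reachable turn floor for a family is
`max(4, 2(min(w,h)−1) − 2(p−1))`; `feasible_turn_range()` exposes it, the
turn draw in `build_parallel_sets()` samples uniformly from it (383 of the
395 nominal tuples are reachable; the 12 excluded lie on large boards with
few paths and few turns, where full covers are provably impossible or
nearly so), and requesting an unreachable tuple fails with an explicit
error naming the level. Generated solutions are verified against
`validate_solution()` on every call and, on boards of at most 25 cells,
can be cross-checked against an exhaustive backtracking solver
(`solve_brute_force()`, compiled code) that enumerates *every* full-cover
solution. Puzzle uniqueness is deliberately not required: random
full-cover boards may admit several covers, and the stored solution is a
reference, not a uniqueness claim.

## Numerical choices

- **Coordinates** are 0-based `(col, row)` with origin top-left; pixels
  have y increasing downward; cells are half-open pixel rectangles, so a
  point on the board's right/bottom edge is off-board.
- **Timestamps** are integer milliseconds; durations are reported in
  seconds. TST/MET/MPT conservation therefore holds to within 1 ms.
- **RDP tolerance** defaults to `0.25 * cell_size`: comfortably below the
  half-cell deviation of a true corner, comfortably above realistic touch
  jitter. It is exposed in `compute_level_metrics()`.
- **MVE aggregation** is the unweighted mean of per-sub-path arc speeds;
  the alternative (total arc / total time) is available via
  `mve_weighting = "total"`. Zero-duration sub-paths are excluded with a
  warning.
- **MDC axis semantics**: reversals are counted along the sub-path's own
  task axis, following the pointing-device accuracy literature from which
  the measure descends; orthogonal-axis reversals are computed but
  reported separately (`mdc_orth`) as a diagnostic. Zero velocity
  components are skipped when counting sign changes.
- **False moves** are detected from snapshots: the cells a move set are
  those that changed to its label during the move and still carried it at
  release; the move is false iff that cell set differs from the final
  labeling of its path or is touched by any later state change ("correct
  but deleted" is false).
- **Ties** in all rank procedures use average ranks; the Kruskal–Wallis H
  always applies the tie correction. Post hoc rank-mean comparisons use
  the critical difference at `z = qnorm(1 − alpha / (k(k−1)))` and report
  adjusted p values capped at 1.
- **Degenerate inputs** degrade explicitly: identical groups give H = 0,
  p = 1; a constant vector flags the Spearman coefficient as undefined; a
  constant covariate makes the partial correlation fall back to the simple
  one (flagged with a note); levels without a solved event are marked
  unsolved and excluded from session aggregation, which uses median and
  IQR (plus SD) across solved levels.

## What the simulator emulates — and what it does not

`simulate_level()` plays the reference solution path by path: a log-normal
planning pause, then a drag along the cell centres at log-normally
perturbed speed, sampled at 60 Hz (a typical tablet digitizer; one sample
is also emitted exactly at each path corner, since uniform sampling alone
cuts corners and biases arc length low). Orthogonal Gaussian jitter models
touch noise. Along-axis *backtrack trains* — every second sample of a
short run pulled back by 1.5 sampling steps — inject exactly `2m` velocity
sign reversals per train, collinearly, so they can never masquerade as RDP
turns; their count is recorded as ground truth. With probability
`error_prob` a pair is first drawn wrongly (a deviating or truncated stub)
and cleared when the correct path is redrawn from its start dot, matching
the game rule that redrawing/crossing severs a path; each such error
contributes exactly one false move and one excess move.

Planning pauses are placed before each path's first touch so they land in
MPT by construction; the pause before the very first touch is excluded
from the ground-truth MPT because TST starts at first touch.

The five archetypes (`YA`, `OA`, `OOA`, `PD`, `HD`) are illustrative
presets, not fits. Against the group medians such instruments report,
simulated short-set medians reproduce the group *ordering* on all seven
measures and land within ±50% for TST, MPT, MVE, false and excess moves.
Two measures do not magnitude-match by construction: MET (an idealized
player's finger travels the ideal path length, so summed drag time is
short at realistic MVE) and MDC for strongly impaired groups (per-move
sample capacity at 60 Hz bounds how many reversals a drag can carry).
A green cohort-discrimination test therefore establishes that the pipeline
separates groups whose latent parameters differ — not that the simulator
reproduces any particular cohort's absolute numbers. Tremor biomechanics,
learning/fatigue across levels, multi-touch and hint-seeking behaviour are
out of scope.

## Statistical pipeline

Group comparisons default to per-level metric rows from the short-version
levels (the subset all participants complete): tie-corrected
Kruskal–Wallis omnibus test (chi-square approximation, k − 1 df), then
rank-mean post hoc comparisons at familywise alpha 0.05. Concurrent
validity uses Spearman correlations between game metrics and
neuropsychological scores, plus first-order partial Spearman correlations
controlling for age:
ρ<sub>xy·z</sub> = (ρ<sub>xy</sub> − ρ<sub>xz</sub>ρ<sub>yz</sub>) /
√((1 − ρ<sub>xz</sub>²)(1 − ρ<sub>yz</sub>²)), with t-approximation
p values on n − 2 (simple) and n − 3 (partial) degrees of freedom.
Difficulty manipulation is checked by the per-group Spearman correlation
between difficulty rank (area, then paths) and TST.

Calibration properties verified by the acceptance suite: the type-I error
of the H test at alpha 0.05 under the null is 0.05 ± 0.01 over 10⁴
simulations; H agrees with an independent rank-mean computation on all
1680 partitions of n = 9 into three groups of three; the partial
coefficient matches the closed form on a hand-computed 5-point triple; and
a simulated cohort at group sizes 18/14/5 yields a significant omnibus TST
difference and positive difficulty–time correlations in at least 90% of
seeded replicates (run at 25 replicates for runtime; one full replicate
costs about 10 s).

## Known limitations

- Turn-total feasibility is characterized by a constructive bound, not an
  exact combinatorial criterion; a handful of tuples near the bound might
  be coverable by exotic partitions the generator cannot reach.
- The printed totals in the source protocol ("361 difficulty levels";
  "12/24/40" levels per version) are not derivable from its stated ranges;
  the package follows the ranges (395 tuples; 14/30/55 levels per set) and
  asserts only the reproducible structural counts (25 board sizes, 15
  square families, 3 practice levels).
- MET and MDC magnitudes of heavily impaired players are under-emulated
  (see above); hint events are parsed and counted but never produced by
  the simulator.
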