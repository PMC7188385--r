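# numberlink

Game-based cognitive and motor assessment with maze-like Numberlink (flow)
puzzles, for researchers studying digital biomarkers of aging and
neurodegenerative disease.

Numberlink puzzles are played on a `width x height` grid of cells in which
pairs of identical dots must be connected by continuous, non-crossing,
axis-aligned paths such that every cell of the board ends up covered.
Solving them on a touchscreen interleaves planning (where do the paths go?)
with fine motor execution (dragging them), which makes per-level touch logs
a rich source of performance measures for psychomotor, visuoconstructional
and executive function. This package provides the full instrument as
reusable, testable code:

- **Puzzle generation with graded difficulty.** Difficulty levels are
  tuples `(width, height, paths, turns)` with dimensions 4–8 and both the
  number of paths (dot pairs) and the total number of path turns between 4
  and `max(width, height)`. The generator produces a random full-cover
  reference solution hitting the requested tuple exactly, plus the two
  parallel level sets A/B (identical square levels, alternating non-square
  board orientations), short/medium/long versions, the three-level practice
  block, screening-based version assignment (MoCA and TMT-B cut-offs) and
  difficulty ranking by set size then path count.
- **Session-log formats.** Per level, two delimited text files: a
  time-stamped touch-event stream (`t_ms,x_px,y_px,kind` with kinds
  `down/move/up/hint/solved`) and board-state snapshots (one record per
  cell-state change). Both round-trip exactly.
- **Performance metrics.** Per level: total solving time
  `TST = t_solved - t_first_touch`; motor execution time `MET = sum of
  drag-move durations`; mental planning time `MPT = TST - MET`; false
  moves (drawn paths absent from the final solution, or deleted before it);
  excess moves (`moves - pairs`); and two drag-kinematic measures computed
  on sub-paths delimited by Ramer–Douglas–Peucker-detected turns: mean
  velocity `MVE` (mean sub-path arc length / duration, px/s) and movement
  direction changes `MDC` (along-axis velocity sign reversals).
- **Synthetic players.** A simulator with controllable drag speed, speed
  noise, log-normal planning pauses, orthogonal touch jitter, injected
  along-axis reversals and error (wrong-path-then-correct) probability,
  with named archetypes (`YA`, `OA`, `OOA`, `PD`, `HD`) ordered like the
  groups such instruments are designed to separate. Every injected
  quantity is recorded as ground truth so the metric pipeline is testable
  end to end without participant data.
- **Statistics.** The nonparametric pipeline used with such designs:
  tie-corrected Kruskal–Wallis omnibus tests, rank-mean multiple-comparison
  post hoc tests at familywise alpha, Spearman and age-controlled partial
  Spearman correlations, and per-group difficulty-vs-solving-time rank
  correlations.

## Worked example

```r
library(numberlink)

lvl <- difficulty_level(5, 5, 5, 5)          # (width, height, paths, turns)
puz <- generate_puzzle(lvl, generation_config(seed = 42))
print(puz)
#> <nl_puzzle 5 x 5, 5 pairs, with reference solution>
#> ...BD
#> ..BA.
#> ..C..
#> EE.A.
#> C..D.

sim <- simulate_level(puz, group_archetypes()$OA, board_geometry(), seed = 7)
m <- compute_level_metrics(sim$events, sim$snapshots, puz, board_geometry())
round(m[, c("tst_s","met_s","mpt_s","false_moves","excess_moves","mve_px_s","mdc")], 2)
#>   tst_s met_s mpt_s false_moves excess_moves mve_px_s mdc
#> 1 12.99  1.25 11.74           1            1  1795.04  20
```

Reading: this synthetic older-adult participant solved the 5x5 level in
13.0 s, of which 1.2 s was spent dragging (MET) and 11.7 s planning (MPT);
one path was first drawn wrongly and corrected (1 false move = 1 excess
move); the mean drag velocity was ~1795 px/s with 20 within-sub-path
direction reversals.

A command-line interface covers the same pipeline
(`exec/nlgame generate|levels|simulate|score|stats`, see `?nl_cli`).

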