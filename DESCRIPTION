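Package: numberlink
Title: Numberlink Puzzle Generation and Touchscreen Performance Metrics
Version: 0.1.0
Authors@R:
    person("Numberlink", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for game-based cognitive and motor assessment with
    maze-like Numberlink (flow) puzzles. Generates full-cover puzzles with
    graded difficulty levels defined by board size, number of paths and
    total number of turns; reads and writes per-level session logs
    (time-stamped touch events and board-state snapshots); computes
    solving-time, accuracy and drag-movement metrics (total solving time,
    motor execution time, mental planning time, false and excess moves,
    mean velocity and movement direction changes via Ramer-Douglas-Peucker
    sub-path segmentation); simulates synthetic players with impaired and
    healthy motor/cognitive profiles; and runs the nonparametric group
    comparison and rank-correlation pipeline (Kruskal-Wallis with
    rank-mean post hoc comparisons, Spearman and age-controlled partial
    Spearman correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
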