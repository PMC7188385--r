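# Shared fixtures: all built in code at test time.

# hand-written 4x4 puzzle with a known unique-path layout
fixture_puzzle_4x4 <- function() {
  read_grid_text(c("A..B",
                   "....",
                   "C..D",
                   "CABD"))
}

# a generated puzzle with reference solution, fixed seed
fixture_generated <- function(w = 4, h = 4, p = 4, t = 4, seed = 101) {
  generate_puzzle(difficulty_level(w, h, p, t),
                  generation_config(seed = seed))
}

perfect_profile <- function(speed = 2000, pause = 1) {
  player_profile(drag_speed = speed, speed_cv = 0,
                 plan_pause_mean = pause, plan_pause_sd = 0.3,
                 jitter_sd = 0, reversal_rate = 0, error_prob = 0)
}

# independent oracle: turn count by re-walking the cell sequence with a
# direction-difference scan (no shared code with count_turns)
oracle_turns <- function(path) {
  n <- nrow(path)
  turns <- 0L
  for (i in seq_len(n - 2L)) {
    d1 <- c(path[i + 1L, 1] - path[i, 1], path[i + 1L, 2] - path[i, 2])
    d2 <- c(path[i + 2L, 1] - path[i + 1L, 1], path[i + 2L, 2] - path[i + 1L, 2])
    if (!identical(d1, d2)) turns <- turns + 1L
  }
  turns
}

# independent oracle: minimal-subset polyline simplification by exhaustive
# enumeration (interior subsets), for traces of <= 12 points
oracle_simplify <- function(x, y, epsilon) {
  n <- length(x)
  seg_ok <- function(keep) {
    for (s in seq_len(length(keep) - 1L)) {
      i <- keep[s]; j <- keep[s + 1L]
      if (j > i + 1L) {
        for (k in (i + 1L):(j - 1L)) {
          dx <- x[j] - x[i]; dy <- y[j] - y[i]
          L <- sqrt(dx^2 + dy^2)
          d <- if (L == 0) sqrt((x[k] - x[i])^2 + (y[k] - y[i])^2) else
            abs(dx * (y[i] - y[k]) - (x[i] - x[k]) * dy) / L
          if (d > epsilon) return(FALSE)
        }
      }
    }
    TRUE
  }
  interior <- setdiff(seq_len(n), c(1L, n))
  best <- NULL
  for (size in 0:length(interior)) {
    combos <- if (size == 0L) list(integer(0)) else
      asplit(utils::combn(interior, size), 2L)
    for (cc in combos) {
      keep <- sort(c(1L, cc, n))
      if (seg_ok(keep)) { best <- keep; break }
    }
    if (!is.null(best)) break
  }
  best
}

# rank-mean KW oracle: independent formula route
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(ns * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
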