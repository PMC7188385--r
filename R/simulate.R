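# ---------------------------------------------------------------------------
# Synthetic player: generates touch logs and board snapshots for a puzzle
# under a controllable cognitive/motor profile, so the whole metric and
# statistics pipeline is testable without participant data.
#
# The timeline is built path by path: a log-normal planning pause, then a
# drag along the cell centres of the reference path at noisy speed, with
# orthogonal jitter and optionally injected along-axis backtracks
# (each backtrack contributes exactly 2 velocity sign flips).  With
# probability error_prob a pair is first drawn wrongly (a deviating or
# truncated stub path) and cleared when the correct path is redrawn from
# its start dot, as crossing/redrawing severs paths in the game.
# ---------------------------------------------------------------------------

#' Player profile
#'
#' @param drag_speed Mean drag speed, pixels/second (> 0).
#' @param speed_cv Coefficient of variation of per-move speed.
#' @param plan_pause_mean,plan_pause_sd Mean and SD (seconds) of the
#'   log-normal planning pause preceding each path.
#' @param jitter_sd Orthogonal touch noise per sample, pixels.
#' @param reversal_rate Expected along-axis velocity sign flips per
#'   sub-path (injected as backtracks of 2 flips each).
#' @param error_prob Probability that a pair is first drawn wrongly and
#'   corrected.
#' @param sample_rate Touch sampling rate, Hz (default 60, a typical
#'   tablet digitizer).
#' @return An `nl_profile` list.
#' @export
player_profile <- function(drag_speed = 2000, speed_cv = 0.1,
                           plan_pause_mean = 1, plan_pause_sd = 0.5,
                           jitter_sd = 0, reversal_rate = 0,
                           error_prob = 0, sample_rate = 60) {
  stopifnot(drag_speed > 0, speed_cv >= 0, plan_pause_mean >= 0,
            plan_pause_sd >= 0, jitter_sd >= 0, reversal_rate >= 0,
            error_prob >= 0, error_prob <= 1, sample_rate > 0)
  structure(as.list(environment()), class = "nl_profile")
}

#' Group archetype profiles
#'
#' Named presets emulating the contrast between young adults (YA), older
#' adults (OA), oldest adults (OOA) and patients with Parkinson's (PD) and
#' Huntington's disease (HD): drag speed ordered YA > OA ~ PD > OOA ~ HD,
#' planning pauses and error probability increasing with impairment, and
#' HD maximal in error rate and direction-change load.  Illustrative
#' parameter choices, not a fit to any cohort.
#'
#' @return Named list of [player_profile()]s.
#' @export
group_archetypes <- function() {
  list(
    YA  = player_profile(drag_speed = 2650, speed_cv = 0.10,
                         plan_pause_mean = 1.1, plan_pause_sd = 0.55,
                         jitter_sd = 2, reversal_rate = 10, error_prob = 0.15),
    OA  = player_profile(drag_speed = 1700, speed_cv = 0.12,
                         plan_pause_mean = 2.8, plan_pause_sd = 1.4,
                         jitter_sd = 3, reversal_rate = 15, error_prob = 0.20),
    OOA = player_profile(drag_speed = 1150, speed_cv = 0.15,
                         plan_pause_mean = 4.9, plan_pause_sd = 2.4,
                         jitter_sd = 4, reversal_rate = 20, error_prob = 0.35),
    PD  = player_profile(drag_speed = 1650, speed_cv = 0.15,
                         plan_pause_mean = 2.6, plan_pause_sd = 1.3,
                         jitter_sd = 4, reversal_rate = 19, error_prob = 0.25),
    HD  = player_profile(drag_speed = 1050, speed_cv = 0.20,
                         plan_pause_mean = 6.7, plan_pause_sd = 3.3,
                         jitter_sd = 5, reversal_rate = 54, error_prob = 0.95))
}

cell_center <- function(cells, geometry) {
  cbind(x = geometry$origin_x + (cells[, 1] + 0.5) * geometry$cell_size,
        y = geometry$origin_y + (cells[, 2] + 0.5) * geometry$cell_size)
}

# sample a drag along the cell-centre polyline of `cells`
# returns events rows, arc length drawn, injected flip count
sample_drag <- function(cells, t_start, profile, geometry) {
  ctr <- cell_center(cells, geometry)
  seglen <- sqrt(diff(ctr[, 1])^2 + diff(ctr[, 2])^2)
  cum <- c(0, cumsum(seglen))
  L <- cum[length(cum)]
  v <- profile$drag_speed *
    exp(rnorm(1, -0.5 * log(1 + profile$speed_cv^2),
              sqrt(log(1 + profile$speed_cv^2))))
  dur_ms <- max(L / v * 1000, 3000 / profile$sample_rate)
  step_ms <- 1000 / profile$sample_rate
  tt <- seq(0, dur_ms, by = step_ms)
  if (tt[length(tt)] < dur_ms) tt <- c(tt, dur_ms)
  # emit a sample exactly at each polyline corner: uniform sampling alone
  # cuts corners and systematically shortens the drawn arc
  corner_arc <- cum[corner_flags(cells)]
  if (length(corner_arc))
    tt <- sort(unique(c(tt, corner_arc / L * dur_ms)))
  s <- pmin(tt / dur_ms, 1) * L

  # inject along-axis backtrack trains: pulling every second sample of a
  # short run back by 1.5 sampling steps yields a sawtooth with exactly
  # 2 m velocity sign flips for a train of m pulled samples; trains stay
  # >= 3 samples away from the polyline corners that delimit sub-paths,
  # so the flips cannot straddle an RDP-detected turn
  flips <- 0L
  if (profile$reversal_rate > 0 && length(s) >= 9L) {
    turn_arc <- cum[c(TRUE, corner_flags(cells)[-c(1, nrow(cells))], TRUE)]
    n_seg <- length(turn_arc) - 1L
    target <- rpois(1, profile$reversal_rate * n_seg)
    step_arc <- L / length(s)
    seg_of <- findInterval(s, turn_arc, rightmost.closed = TRUE)
    free <- rep(FALSE, length(s))
    idx <- 4:(length(s) - 4L)
    free[idx] <- s[idx] > 2 * step_arc & s[idx] < L - 2 * step_arc &
      seg_of[idx - 3L] == seg_of[idx + 3L]
    while (target >= 2L && any(free)) {
      open <- which(free)
      j <- open[sample.int(length(open), 1L)]
      m <- 1L
      while (m < 4L && 2L * (m + 1L) <= target &&
             j + 2L * m <= length(s) - 4L && free[j + 2L * m])
        m <- m + 1L
      at <- j + 2L * (seq_len(m) - 1L)
      s[at] <- s[at] - 1.5 * step_arc
      flips <- flips + 2L * m
      target <- target - 2L * m
      free[max(j - 4L, 1L):min(j + 2L * m + 3L, length(s))] <- FALSE
    }
  }

  # arc position -> coordinates, orthogonal jitter per sample
  seg_idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                  length(seglen))
  frac <- (s - cum[seg_idx]) / seglen[seg_idx]
  x <- ctr[seg_idx, 1] + frac * (ctr[seg_idx + 1L, 1] - ctr[seg_idx, 1])
  y <- ctr[seg_idx, 2] + frac * (ctr[seg_idx + 1L, 2] - ctr[seg_idx, 2])
  if (profile$jitter_sd > 0) {
    horiz <- abs(ctr[seg_idx + 1L, 1] - ctr[seg_idx, 1]) >
             abs(ctr[seg_idx + 1L, 2] - ctr[seg_idx, 2])
    jit <- rnorm(length(s), 0, profile$jitter_sd)
    jit[c(1L, length(jit))] <- 0        # endpoints stay on the dots
    y[horiz] <- y[horiz] + jit[horiz]
    x[!horiz] <- x[!horiz] + jit[!horiz]
  }
  kinds <- c("down", rep("move", length(s) - 2L), "up")
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  list(events = data.frame(t_ms = as.integer(round(t_start + tt)),
                           x_px = round(x), y_px = round(y), kind = kinds),
       arc = arc, duration_ms = dur_ms, flips = flips,
       enter_t = t_start + tt, s = s)
}

#' Simulate one level
#'
#' @param puzzle An [nl_puzzle()] with reference solution.
#' @param profile A [player_profile()].
#' @param geometry A [board_geometry()] the board fits into.
#' @param seed Optional integer seed (fully deterministic given the seed).
#' @return List with `events` (touch-event data frame), `snapshots`
#'   (snapshot list) and `ground_truth`: the injected quantities
#'   (`tst_ms`, `met_ms`, `mpt_ms`, `error_moves`, `flips`, `n_moves`,
#'   `arc_per_move`, `speed_per_move`).
#' @export
simulate_level <- function(puzzle, profile, geometry = board_geometry(),
                           seed = NULL) {
  stopifnot(inherits(puzzle, "nl_puzzle"), !is.null(puzzle$solution),
            inherits(profile, "nl_profile"))
  check_geometry_fits(geometry, puzzle$board)
  with_seed(seed, {
    w <- puzzle$board$width; h <- puzzle$board$height
    state <- initial_snapshot(puzzle)$cells
    snapshots <- list(structure(list(t_ms = 0L, cells = state),
                                class = "nl_snapshot"))
    push_snap <- function(t, cells) {
      snapshots[[length(snapshots) + 1L]] <<- structure(
        list(t_ms = as.integer(round(t)), cells = cells),
        class = "nl_snapshot")
      state <<- cells
    }
    events <- list()
    push_events <- function(df) events[[length(events) + 1L]] <<- df

    order_lb <- sample(names(puzzle$solution))
    t <- 0
    gt <- list(pauses_ms = 0, met_ms = 0, error_moves = 0L, flips = 0L,
               n_moves = 0L, arc = numeric(0), speed = numeric(0))
    first_down_t <- NA_real_

    draw_move <- function(cells, label, set_interior) {
      drag <- sample_drag(cells, t, profile, geometry)
      push_events(drag$events)
      # state changes: cells become labelled as the drag first reaches them
      ctr <- cell_center(cells, geometry)
      cell_arc <- c(0, cumsum(sqrt(diff(ctr[, 1])^2 + diff(ctr[, 2])^2)))
      smax <- cummax(drag$s)
      for (ci in set_interior) {
        k <- which(smax >= cell_arc[ci])[1]
        if (is.na(k)) k <- length(drag$s)
        cur <- state
        cur[cells[ci, 2] + 1L, cells[ci, 1] + 1L] <- label
        push_snap(drag$enter_t[k], cur)
      }
      gt$met_ms <<- gt$met_ms + (drag$events$t_ms[nrow(drag$events)] -
                                   drag$events$t_ms[1])
      gt$flips <<- gt$flips + drag$flips
      gt$n_moves <<- gt$n_moves + 1L
      gt$arc <<- c(gt$arc, drag$arc)
      gt$speed <<- c(gt$speed, drag$arc / (drag$duration_ms / 1000))
      if (is.na(first_down_t)) first_down_t <<- drag$events$t_ms[1]
      t <<- drag$events$t_ms[nrow(drag$events)]
    }

    pause <- function() {
      p <- rlnorm(1, lnorm_mu(profile$plan_pause_mean, profile$plan_pause_sd),
                  lnorm_sigma(profile$plan_pause_mean, profile$plan_pause_sd))
      if (!is.na(first_down_t)) gt$pauses_ms <<- gt$pauses_ms + p * 1000
      t <<- t + p * 1000
    }

    for (lb in order_lb) {
      path <- puzzle$solution[[lb]]
      pause()
      if (profile$error_prob > 0 && runif(1) < profile$error_prob) {
        wrong <- wrong_route(path, state, puzzle, w, h)
        if (!is.null(wrong)) {
          draw_move(wrong$cells, lb, wrong$set_interior)
          gt$error_moves <- gt$error_moves + 1L
          pause()
          # redrawing from the start dot clears the wrong path
          cur <- state
          for (ci in wrong$set_interior) {
            cur[wrong$cells[ci, 2] + 1L, wrong$cells[ci, 1] + 1L] <- "0"
          }
          push_snap(t, cur)
        }
      }
      draw_move(path, lb, seq(2L, nrow(path) - 1L))
    }
    push_events(data.frame(t_ms = as.integer(round(t)), x_px = NA_real_,
                           y_px = NA_real_, kind = "solved"))
    ev <- do.call(rbind, events)
    rownames(ev) <- NULL
    gt$tst_ms <- ev$t_ms[nrow(ev)] - first_down_t
    gt$mpt_ms <- gt$tst_ms - gt$met_ms
    list(events = ev, snapshots = snapshots, ground_truth = gt)
  })
}

lnorm_mu <- function(m, s) {
  if (m <= 0) return(-Inf)
  log(m^2 / sqrt(m^2 + s^2))
}
lnorm_sigma <- function(m, s) {
  if (m <= 0) return(0)
  sqrt(log(1 + s^2 / m^2))
}

# a wrong first attempt for a pair: deviate off the true path into empty
# non-dot cells when possible, otherwise a truncated stub of the true path
wrong_route <- function(path, state, puzzle, w, h) {
  pr <- puzzle$pairs
  dot_mat <- matrix(FALSE, nrow = h, ncol = w)
  dot_mat[cbind(c(pr$ay, pr$by) + 1L, c(pr$ax, pr$bx) + 1L)] <- TRUE
  on_path <- matrix(FALSE, nrow = h, ncol = w)
  on_path[cbind(path[, 2] + 1L, path[, 1] + 1L)] <- TRUE
  for (from in list(path, path[nrow(path):1, , drop = FALSE])) {
    a <- from[1, ]
    nbs <- rbind(a + c(1L, 0L), a + c(-1L, 0L), a + c(0L, 1L), a + c(0L, -1L))
    nbs <- nbs[nbs[, 1] >= 0 & nbs[, 1] < w & nbs[, 2] >= 0 & nbs[, 2] < h,
               , drop = FALSE]
    ok <- !on_path[cbind(nbs[, 2] + 1L, nbs[, 1] + 1L)] &
          !dot_mat[cbind(nbs[, 2] + 1L, nbs[, 1] + 1L)] &
          state[cbind(nbs[, 2] + 1L, nbs[, 1] + 1L)] == "0"
    nbs <- nbs[ok, , drop = FALSE]
    if (nrow(nbs)) {
      dev <- nbs[sample.int(nrow(nbs), 1L), ]
      cells <- rbind(a, dev)
      colnames(cells) <- c("col", "row")
      storage.mode(cells) <- "integer"
      return(list(cells = cells, set_interior = 2L))
    }
  }
  # stub: cover only the first interior cell of the true path
  cells <- path[1:2, , drop = FALSE]
  list(cells = cells, set_interior = 2L)
}

#' Simulate a cohort of synthetic participants
#'
#' Per participant: a profile sampled around the group archetype, one
#' session over all puzzles of the level set, and nominal covariates (age,
#' MoCA, TMT-A/B, SMT) drawn from group-typical ranges.  Deterministic
#' given the seed.
#'
#' @param puzzles List of [nl_puzzle()]s (one per level, e.g. from
#'   [generate_levelset_puzzles()]).
#' @param level_ranks Integer difficulty rank per puzzle (same length).
#' @param archetypes Named list of [player_profile()]s (names = groups).
#' @param n_per_group Named or unnamed integer vector of group sizes.
#' @param geometry A [board_geometry()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, per-participant session
#'   files (`touch_<level>.csv`, `snap_<level>.csv`) and a
#'   `covariates.csv` table are written.
#' @return List with `covariates` (data frame), `sessions` (per
#'   participant: list of per-level `simulate_level()` results) and
#'   `metrics` (long data frame of per-level metrics rows with
#'   participant, group and level rank).
#' @export
simulate_cohort <- function(puzzles, level_ranks, archetypes, n_per_group,
                            geometry = board_geometry(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(length(puzzles) == length(level_ranks))
  if (is.null(names(n_per_group))) names(n_per_group) <- names(archetypes)
  cov_rows <- list(); sessions <- list(); met_rows <- list()
  pid <- 0L
  for (g in names(n_per_group)) {
    base <- archetypes[[g]]
    for (k in seq_len(n_per_group[[g]])) {
      pid <- pid + 1L
      pseed <- (seed %% 100000L) * 10000L + pid
      prof <- with_seed(pseed, participant_profile(base))
      covs <- with_seed(pseed + 5000L, participant_covariates(g))
      id <- sprintf("P%03d", pid)
      cov_rows[[pid]] <- cbind(data.frame(participant = id, group = g), covs)
      sess <- lapply(seq_along(puzzles), function(i)
        simulate_level(puzzles[[i]], prof, geometry,
                       seed = pseed + 100L + i))
      sessions[[id]] <- sess
      met <- do.call(rbind, lapply(seq_along(sess), function(i)
        cbind(data.frame(participant = id, group = g,
                         level_rank = level_ranks[i]),
              compute_level_metrics(sess[[i]]$events, sess[[i]]$snapshots,
                                    puzzles[[i]], geometry))))
      met_rows[[pid]] <- met
      if (!is.null(out_dir)) {
        pdir <- file.path(out_dir, id)
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_along(sess)) {
          write_touch_log(sess[[i]]$events,
                          file.path(pdir, sprintf("touch_%02d.csv", i)))
          write_snapshots(sess[[i]]$snapshots,
                          file.path(pdir, sprintf("snap_%02d.csv", i)))
        }
      }
    }
  }
  covariates <- do.call(rbind, cov_rows)
  if (!is.null(out_dir))
    write.csv(covariates, file.path(out_dir, "covariates.csv"),
              row.names = FALSE)
  list(covariates = covariates, sessions = sessions,
       metrics = do.call(rbind, met_rows))
}

participant_profile <- function(base) {
  player_profile(
    drag_speed = base$drag_speed * rlnorm(1, 0, 0.08),
    speed_cv = base$speed_cv,
    plan_pause_mean = base$plan_pause_mean * rlnorm(1, 0, 0.15),
    plan_pause_sd = base$plan_pause_sd,
    jitter_sd = base$jitter_sd,
    reversal_rate = base$reversal_rate * rlnorm(1, 0, 0.15),
    error_prob = min(base$error_prob * rlnorm(1, 0, 0.15), 1),
    sample_rate = base$sample_rate)
}

# group-typical covariate ranges (age, MoCA 0-30, TMT-A/B seconds, SMT s)
COVARIATE_RANGES <- list(
  YA  = list(age = c(21.8, 3.3),  moca = c(28.6, 1.5), tmt_a = c(26.4, 9.4),
             tmt_b = c(50.8, 19.3),  smt = c(14.4, 3.1)),
  OA  = list(age = c(71.1, 4.3),  moca = c(27.2, 2.9), tmt_a = c(36.2, 7.7),
             tmt_b = c(107.7, 43.2), smt = c(32.2, 10.1)),
  OOA = list(age = c(89.9, 3.5),  moca = c(23.4, 4.2), tmt_a = c(66.9, 33.1),
             tmt_b = c(145.5, 18.7), smt = c(43.4, 20.3)),
  PD  = list(age = c(67.5, 7.0),  moca = c(26.3, 3.4), tmt_a = c(45.3, 11.5),
             tmt_b = c(122.5, 68.7), smt = c(24.8, 11.1)),
  HD  = list(age = c(49.4, 13.3), moca = c(18.3, 6.2), tmt_a = c(98.2, 80.0),
             tmt_b = c(227.0, 17.9), smt = c(50.4, 35.2)))

participant_covariates <- function(group) {
  rg <- COVARIATE_RANGES[[group]]
  trunc_norm <- function(ms, lo, hi)
    min(max(rnorm(1, ms[1], ms[2]), lo), hi)
  data.frame(age = round(trunc_norm(rg$age, 18, 100)),
             moca = round(trunc_norm(rg$moca, 0, 30)),
             tmt_a = round(trunc_norm(rg$tmt_a, 5, 300), 1),
             tmt_b = round(trunc_norm(rg$tmt_b, 10, 400), 1),
             smt = round(trunc_norm(rg$smt, 5, 300), 1))
}
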