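# per-level performance measures

test_that("time metrics: TST, MET, MPT basics", {
  ev <- data.frame(t_ms = c(1000L, 5000L, 8550L),
                   x_px = c(0, 10, NA), y_px = c(0, 10, NA),
                   kind = c("down", "up", "solved"))
  expect_equal(as.numeric(total_solving_time(ev)), 7.55)
  ev2 <- ev[ev$kind != "solved", ]
  tst2 <- total_solving_time(ev2)
  expect_true(is.na(tst2))
  expect_false(attr(tst2, "solved"))

  m <- list(structure(list(duration = 0.4), class = "nl_move"),
            structure(list(duration = 0.6), class = "nl_move"))
  expect_equal(motor_execution_time(m), 1.0)
  expect_equal(motor_execution_time(list()), 0)

  expect_equal(mental_planning_time(10, 4), 6)
  expect_equal(mental_planning_time(5, 5), 0)
  expect_error(mental_planning_time(3, 4), "exceeds")
})

test_that("TST/MET/MPT recover the simulator's schedule", {
  puz <- fixture_generated(5, 5, 5, 5)
  geom <- board_geometry()
  for (seed in 1:10) {
    sim <- simulate_level(puz, perfect_profile(speed = 1500, pause = 2),
                          geom, seed = seed)
    m <- compute_level_metrics(sim$events, sim$snapshots, puz, geom)
    gt <- sim$ground_truth
    expect_equal(m$tst_s, gt$tst_ms / 1000, tolerance = 1e-9)
    expect_equal(m$met_s, gt$met_ms / 1000, tolerance = 1e-9)
    # scheduled pauses land in MPT (within 1 sample period per move)
    expect_equal(m$mpt_s, gt$pauses_ms / 1000,
                 tolerance = 0.02 * gt$n_moves / (gt$pauses_ms / 1000))
    expect_equal(m$tst_s, m$met_s + m$mpt_s, tolerance = 1e-9)
  }
})

test_that("excess move arithmetic and hint exclusion", {
  expect_equal(excess_moves(7, 5), 2)
  expect_equal(excess_moves(5, 5), 0)
  expect_equal(excess_moves(4, 5, hint_pairs = 1), 0)
  expect_error(excess_moves(3, 5), "fewer moves")
})

test_that("classify_moves flags drawn-then-deleted and wrong paths", {
  puz <- fixture_generated(5, 5, 4, 5)
  geom <- board_geometry()
  # error-free session: (0, k)
  sim <- simulate_level(puz, perfect_profile(), geom, seed = 4)
  moves <- segment_moves(sim$events)
  cls <- classify_moves(moves, sim$snapshots, puz)
  expect_equal(cls$false_count, 0)
  expect_equal(cls$correct_count, nrow(puz$pairs))

  # injected errors are recovered exactly (drawn, then cleared, then redrawn)
  prof <- perfect_profile()
  prof$error_prob <- 1
  for (seed in 5:9) {
    sime <- simulate_level(puz, prof, geom, seed = seed)
    movese <- segment_moves(sime$events)
    clse <- classify_moves(movese, sime$snapshots, puz)
    expect_equal(clse$false_count, sime$ground_truth$error_moves)
    expect_gte(clse$false_count, 1)
    expect_equal(excess_moves(length(movese), nrow(puz$pairs)),
                 sime$ground_truth$error_moves)
  }

  # mismatched final snapshot is an error
  snaps <- sim$snapshots
  snaps[[length(snaps)]]$cells[1, 1] <- "0"
  expect_error(classify_moves(moves, snaps, puz), "final snapshot")
})

test_that("RDP retains exactly the trace corners and matches the exhaustive oracle", {
  # collinear points: endpoints only
  expect_equal(rdp_simplify(0:9, rep(0, 10), 1), c(1, 10))
  # perfect L: one interior vertex at the corner
  xs <- c(0, 10, 20, 30, 30, 30); ys <- c(0, 0, 0, 0, 10, 20)
  expect_equal(rdp_simplify(xs, ys, 5), c(1, 4, 6))

  set.seed(13)
  for (rep in 1:20) {
    # rectilinear trace over <= 12 points with jitter < eps/2
    eps <- 8
    nseg <- sample(1:3, 1)
    x <- 0; y <- 0; horiz <- TRUE
    for (s in seq_len(nseg)) {
      steps <- sample(2:4, 1)
      for (k in seq_len(steps)) {
        if (horiz) x <- c(x, x[length(x)] + 20) else x <- c(x, x[length(x)])
        if (!horiz) y <- c(y, y[length(y)] + 20) else y <- c(y, y[length(y)])
      }
      horiz <- !horiz
    }
    x <- x[1:min(length(x), 12)]; y <- y[1:min(length(y), 12)]
    xj <- x + runif(length(x), -eps / 2.5, eps / 2.5)
    yj <- y + runif(length(y), -eps / 2.5, eps / 2.5)
    got <- rdp_simplify(xj, yj, eps)
    want <- oracle_simplify(xj, yj, eps)
    expect_equal(got, want)
  }
})

test_that("sub-path segmentation and kinematics", {
  mk_move <- function(t, x, y) structure(
    list(events = data.frame(t_ms = t, x_px = x, y_px = y,
                             kind = c("down", rep("move", length(t) - 2), "up")),
         duration = (t[length(t)] - t[1]) / 1000), class = "nl_move")

  straight <- mk_move(seq(0, 500, 100), seq(0, 500, 100), rep(0, 6))
  sp <- segment_subpaths(straight, c(1, 6))
  expect_length(sp, 1)
  expect_equal(sp[[1]]$axis, "horizontal")
  expect_equal(mean_velocity(sp), 1000)  # 500 px in 0.5 s

  ell <- mk_move(seq(0, 600, 100), c(0, 100, 200, 300, 300, 300, 300),
                 c(0, 0, 0, 0, 100, 200, 300))
  idx <- rdp_simplify(ell$events$x_px, ell$events$y_px, 10)
  sp2 <- segment_subpaths(ell, idx)
  expect_length(sp2, 2)
  expect_equal(vapply(sp2, `[[`, "", "axis"), c("horizontal", "vertical"))

  # n detected turns -> n + 1 sub-paths
  expect_length(segment_subpaths(straight, c(1, 3, 5, 6)), 3)

  # mean of two sub-path speeds
  two <- list(structure(list(duration = 1, arc_length = 800,
                             points = NULL, axis = "horizontal"),
                        class = "nl_subpath"),
              structure(list(duration = 1, arc_length = 1200,
                             points = NULL, axis = "horizontal"),
                        class = "nl_subpath"))
  expect_equal(mean_velocity(two), 1000)
  expect_equal(mean_velocity(two, weighting = "total"), 1000)

  # monotone sub-path: 0 reversals; advance-backup-advance: 2
  mono <- segment_subpaths(straight, c(1, 6))
  expect_equal(movement_direction_changes(mono)$mdc, 0)
  wob <- mk_move(seq(0, 500, 100), c(0, 100, 200, 150, 250, 350), rep(0, 6))
  expect_equal(movement_direction_changes(segment_subpaths(wob, c(1, 6)))$mdc, 2)
})

test_that("session summary uses medians over solved levels", {
  lm <- data.frame(tst_s = c(5, 7, 9), met_s = c(2, 2, 2), mpt_s = c(3, 5, 7),
                   false_moves = 0L, excess_moves = 0L, hints = 0L,
                   mve_px_s = 1000, mdc = 0L, mdc_orth = 0L, n_moves = 4L,
                   solved = TRUE)
  sm <- summarize_session(lm)
  expect_equal(sm$median[sm$measure == "tst_s"], 7)
  expect_equal(sm$iqr[sm$measure == "mve_px_s"], 0)
  expect_equal(sm$sd[sm$measure == "mve_px_s"], 0)

  # sort-based median oracle on random metric sets
  set.seed(21)
  for (i in 1:50) {
    v <- rexp(sample(3:15, 1)) * 10
    lmr <- lm[rep(1, length(v)), ]
    lmr$tst_s <- v
    got <- summarize_session(lmr)
    want <- sort(v)[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0)
      want <- mean(sort(v)[length(v) / 2 + c(0, 1)])
    expect_equal(got$median[got$measure == "tst_s"], want)
  }

  lm$solved <- FALSE
  expect_error(summarize_session(lm), "no solved level")
})

test_that("metric conservation and error monotonicity on simulated sessions", {
  puz <- fixture_generated(5, 4, 4, 4)
  geom <- board_geometry()
  base <- perfect_profile(speed = 1800, pause = 1.5)
  err <- base; err$error_prob <- 1
  for (seed in 31:36) {
    m0 <- with(simulate_level(puz, base, geom, seed = seed),
               compute_level_metrics(events, snapshots, puz, geom))
    m1 <- with(simulate_level(puz, err, geom, seed = seed),
               compute_level_metrics(events, snapshots, puz, geom))
    expect_equal(m0$tst_s, m0$met_s + m0$mpt_s, tolerance = 1e-6)
    expect_equal(m1$tst_s, m1$met_s + m1$mpt_s, tolerance = 1e-6)
    # injected error moves add strictly to the error counts and, with a
    # deterministic drag speed, to MET (the correct-move durations match)
    expect_gte(m1$false_moves, m0$false_moves + 1)
    expect_gte(m1$excess_moves, m0$excess_moves + 1)
    expect_gt(m1$met_s, m0$met_s)
  }
})
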