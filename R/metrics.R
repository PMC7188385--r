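# ---------------------------------------------------------------------------
# The seven per-level performance measures:
#   TST  total solving time      first touch -> solved event, seconds
#   MET  motor execution time    summed drag-move durations, seconds
#   MPT  mental planning time    TST - MET, seconds
#   false moves                  drawn paths absent from the final solution,
#                                or deleted/overwritten before it
#   excess moves                 total moves minus number of dot pairs
#   MVE  mean velocity           average sub-path arc speed, pixels/second
#   MDC  movement direction changes  along-axis velocity sign reversals
#                                within RDP-detected sub-paths
# ---------------------------------------------------------------------------

#' Total solving time
#'
#' Time elapsed from the initial touch to the solved puzzle, in seconds.
#'
#' @param events Touch-event data frame.
#' @return TST in seconds, or `NA` (with attribute `solved = FALSE`) when
#'   the log has no solved event.
#' @export
total_solving_time <- function(events) {
  downs <- events$t_ms[events$kind == "down"]
  if (!length(downs)) stop("log contains no touch down event")
  solved <- events$t_ms[events$kind == "solved"]
  if (!length(solved))
    return(structure(NA_real_, solved = FALSE))
  structure((solved[length(solved)] - downs[1]) / 1000, solved = TRUE)
}

#' Motor execution time
#'
#' Sum of the durations of all drag moves (false moves included: they are
#' moves), in seconds.
#'
#' @param moves List of moves from [segment_moves()].
#' @return MET in seconds (0 when there are no moves).
#' @export
motor_execution_time <- function(moves) {
  if (!length(moves)) return(0)
  sum(vapply(moves, `[[`, numeric(1), "duration"))
}

#' Mental planning time
#'
#' @param tst,met Total solving and motor execution times, seconds.
#' @return `tst - met` in seconds.
#' @export
mental_planning_time <- function(tst, met) {
  if (met > tst + 1e-9)
    stop(sprintf("MET (%.3f s) exceeds TST (%.3f s): inconsistent segmentation",
                 met, tst))
  max(tst - met, 0)
}

# ---------------------------------------------------------------------------
# Move classification (snapshot-based)
# ---------------------------------------------------------------------------

snapshot_times <- function(snapshots)
  vapply(snapshots, `[[`, integer(1), "t_ms")

state_before <- function(snapshots, t) {
  ts <- snapshot_times(snapshots)
  i <- max(which(ts < t), 1L)
  snapshots[[i]]$cells
}

state_at <- function(snapshots, t) {
  ts <- snapshot_times(snapshots)
  idx <- which(ts <= t)
  if (!length(idx)) return(snapshots[[1]]$cells)
  snapshots[[max(idx)]]$cells
}

# cells (matrix indices) a move set to its label: changed to `lb` at some
# snapshot within (t_down - 1, t_up] and still `lb` at t_up
move_cells_set <- function(move, snapshots) {
  t0 <- move$events$t_ms[1]
  t1 <- move$events$t_ms[nrow(move$events)]
  ts <- snapshot_times(snapshots)
  before <- state_before(snapshots, t0)
  after <- state_at(snapshots, t1)
  inside <- which(ts >= t0 & ts <= t1)
  became <- matrix(FALSE, nrow = nrow(before), ncol = ncol(before))
  prev <- before
  for (i in inside) {
    cur <- snapshots[[i]]$cells
    became <- became | (cur != prev & cur != "0")
    prev <- cur
  }
  set <- became & (after != "0")
  if (!any(set)) return(list(label = NA_character_, cells = integer(0),
                             after = after))
  lb <- names(sort(table(after[set]), decreasing = TRUE))[1]
  list(label = lb, cells = which(set & after == lb), after = after)
}

#' Classify moves as false or correct
#'
#' A move is false iff the cells it set are not identical to a solution
#' path at level end, or were later cleared or overwritten before the
#' puzzle was solved (a correct path deleted before the end counts as
#' false).  Detection is snapshot-based: the cells a move set are compared
#' against the final labeling and all subsequent snapshots.
#'
#' @param moves List of moves from [segment_moves()].
#' @param snapshots Snapshot list covering the level.
#' @param puzzle The [nl_puzzle()] played (reference solution required).
#' @return List with `false_count`, `correct_count` and the per-move
#'   logical vector `is_false`.
#' @export
classify_moves <- function(moves, snapshots, puzzle) {
  stopifnot(!is.null(puzzle$solution))
  final <- snapshots[[length(snapshots)]]$cells
  target <- solution_labeling(puzzle)
  if (!all(final == target))
    stop("final snapshot does not match the reference solution labeling")
  ts <- snapshot_times(snapshots)
  pr <- puzzle$pairs
  dot_idx <- c((pr$ax) * nrow(final) + pr$ay + 1L,
               (pr$bx) * nrow(final) + pr$by + 1L)
  dot_lab <- rep(pr$label, 2L)
  is_false <- vapply(moves, function(mv) {
    info <- move_cells_set(mv, snapshots)
    if (is.na(info$label)) return(TRUE)          # move that drew nothing
    lb <- info$label
    want <- setdiff(which(target == lb), dot_idx[dot_lab == lb])
    if (!setequal(info$cells, want)) return(TRUE)
    # deleted/overwritten afterwards?
    t1 <- mv$events$t_ms[nrow(mv$events)]
    later <- which(ts > t1)
    ref <- state_at(snapshots, t1)
    for (i in later) {
      if (any(snapshots[[i]]$cells[info$cells] != ref[info$cells]))
        return(TRUE)
    }
    FALSE
  }, TRUE)
  list(false_count = sum(is_false),
       correct_count = sum(!is_false),
       is_false = is_false)
}

#' Excess moves
#'
#' Total number of moves minus the number of dot pairs (pairs completed by
#' a hint are first excluded from the pair count).
#'
#' @param total_moves Number of segmented moves.
#' @param n_pairs Number of dot pairs.
#' @param hint_pairs Pairs completed via hints (default 0).
#' @return Non-negative excess-move count; a negative result on a solved
#'   level is an error.
#' @export
excess_moves <- function(total_moves, n_pairs, hint_pairs = 0L) {
  out <- total_moves - (n_pairs - hint_pairs)
  if (out < 0L)
    stop("fewer moves than dot pairs on a solved level: inconsistent log")
  out
}

# ---------------------------------------------------------------------------
# Ramer-Douglas-Peucker simplification and sub-path kinematics
# ---------------------------------------------------------------------------

perp_dist <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  abs(dx * (y1 - y) - (x1 - x) * dy) / sqrt(L2)
}

#' Ramer-Douglas-Peucker polyline simplification
#'
#' Standard recursive maximum-perpendicular-distance simplification.  The
#' endpoints are always retained; the retained interior vertices are the
#' detected turns of a drag trace.
#'
#' @param x,y Coordinate vectors (>= 2 points).
#' @param epsilon Tolerance in pixels (>= 0).
#' @return Sorted integer indices of the retained vertices.
#' @export
rdp_simplify <- function(x, y, epsilon) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n, epsilon >= 0)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  rec <- function(i, j) {
    if (j <= i + 1L) return(invisible())
    ks <- (i + 1L):(j - 1L)
    d <- vapply(ks, function(k)
      perp_dist(x[k], y[k], x[i], y[i], x[j], y[j]), numeric(1))
    m <- which.max(d)
    if (d[m] > epsilon) {
      k <- ks[m]
      keep[k] <<- TRUE
      rec(i, k); rec(k, j)
    }
    invisible()
  }
  rec(1L, n)
  which(keep)
}

#' Segment a move into axis-aligned sub-paths
#'
#' One sub-path per consecutive pair of retained RDP vertices; straight
#' moves yield a single sub-path.  The axis is assigned from the dominant
#' displacement of the sub-path.  Sub-paths with fewer than 2 samples are
#' merged into their neighbour with a warning.
#'
#' @param move An `nl_move`.
#' @param turn_indices Strictly increasing retained-vertex indices from
#'   [rdp_simplify()] (including the endpoints).
#' @return List of `nl_subpath`s: lists with `points` (a `t`, `x`, `y`
#'   data frame), `axis` (`"horizontal"` or `"vertical"`), `duration`
#'   (seconds) and `arc_length` (pixels).
#' @export
segment_subpaths <- function(move, turn_indices = NULL) {
  ev <- move$events
  pts <- data.frame(t = ev$t_ms, x = ev$x_px, y = ev$y_px)
  if (is.null(turn_indices)) turn_indices <- c(1L, nrow(pts))
  stopifnot(!is.unsorted(turn_indices, strictly = TRUE))
  bounds <- unique(c(1L, turn_indices, nrow(pts)))
  # drop breakpoints that would create sub-paths of < 2 samples
  if (length(bounds) > 2L) {
    ok <- c(TRUE, diff(bounds) >= 1L)
    degenerate <- length(bounds) - sum(ok)
    if (degenerate > 0L)
      warning(sprintf("%d degenerate sub-path boundary(ies) merged", degenerate))
    bounds <- bounds[ok]
  }
  lapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- pts[bounds[i]:bounds[i + 1L], , drop = FALSE]
    dx <- abs(seg$x[nrow(seg)] - seg$x[1])
    dy <- abs(seg$y[nrow(seg)] - seg$y[1])
    structure(list(
      points = seg,
      axis = if (dx >= dy) "horizontal" else "vertical",
      duration = (seg$t[nrow(seg)] - seg$t[1]) / 1000,
      arc_length = sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))),
      class = "nl_subpath")
  })
}

#' Mean velocity over sub-paths
#'
#' Unweighted mean of per-sub-path arc speed (arc length over duration),
#' pixels/second.  Zero-duration sub-paths are excluded with a warning.
#' `weighting = "total"` divides total arc length by total duration
#' instead.
#'
#' @param subpaths List of `nl_subpath`s.
#' @param weighting `"mean"` (default) or `"total"`.
#' @return MVE in pixels/second.
#' @export
mean_velocity <- function(subpaths, weighting = c("mean", "total")) {
  weighting <- match.arg(weighting)
  dur <- vapply(subpaths, `[[`, numeric(1), "duration")
  arc <- vapply(subpaths, `[[`, numeric(1), "arc_length")
  zero <- dur <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-duration sub-path(s) excluded", sum(zero)))
    dur <- dur[!zero]; arc <- arc[!zero]
  }
  if (!length(dur)) return(NA_real_)
  if (weighting == "mean") mean(arc / dur) else sum(arc) / sum(dur)
}

#' Movement direction changes within sub-paths
#'
#' Per sub-path, the number of sign reversals of the velocity component
#' along the sub-path's own axis (zero components are skipped); reversals
#' on the orthogonal axis are returned separately as a diagnostic.
#'
#' @param subpaths List of `nl_subpath`s.
#' @return List with `mdc` (sum of along-axis reversals) and
#'   `orthogonal` (sum of orthogonal-axis reversals).
#' @export
movement_direction_changes <- function(subpaths) {
  count_flips <- function(v) {
    s <- sign(v)
    s <- s[s != 0]
    if (length(s) < 2L) return(0L)
    sum(s[-1] != s[-length(s)])
  }
  along <- 0L; orth <- 0L
  for (sp in subpaths) {
    dx <- diff(sp$points$x); dy <- diff(sp$points$y)
    if (sp$axis == "horizontal") {
      along <- along + count_flips(dx); orth <- orth + count_flips(dy)
    } else {
      along <- along + count_flips(dy); orth <- orth + count_flips(dx)
    }
  }
  list(mdc = along, orthogonal = orth)
}

# ---------------------------------------------------------------------------
# Per-level pipeline and session aggregation
# ---------------------------------------------------------------------------

#' Compute all level metrics from a session log
#'
#' Runs the full per-level pipeline: TST from the event log, move
#' segmentation, MET and MPT, snapshot-based false/excess move counts, and
#' RDP-based movement metrics (MVE, MDC).
#'
#' @param events Touch-event data frame for one level.
#' @param snapshots Snapshot list for the level.
#' @param puzzle The [nl_puzzle()] played (with reference solution).
#' @param geometry The [board_geometry()] used; sets the default RDP
#'   tolerance.
#' @param rdp_epsilon RDP tolerance in pixels; default a quarter cell
#'   (below half a cell so true corners survive, above touch jitter).
#' @param mve_weighting Passed to [mean_velocity()].
#' @return One-row data frame: `tst_s`, `met_s`, `mpt_s`, `false_moves`,
#'   `excess_moves`, `hints`, `mve_px_s`, `mdc`, `mdc_orth`, `n_moves`,
#'   `solved`.
#' @export
compute_level_metrics <- function(events, snapshots, puzzle, geometry,
                                  rdp_epsilon = 0.25 * geometry$cell_size,
                                  mve_weighting = "mean") {
  tst <- total_solving_time(events)
  solved <- isTRUE(attr(tst, "solved"))
  moves <- segment_moves(events)
  met <- motor_execution_time(moves)
  hints <- sum(events$kind == "hint")
  if (!solved)
    return(data.frame(tst_s = NA_real_, met_s = met, mpt_s = NA_real_,
                      false_moves = NA_integer_, excess_moves = NA_integer_,
                      hints = hints, mve_px_s = NA_real_, mdc = NA_integer_,
                      mdc_orth = NA_integer_, n_moves = length(moves),
                      solved = FALSE))
  mpt <- mental_planning_time(as.numeric(tst), met)
  cls <- classify_moves(moves, snapshots, puzzle)
  exc <- excess_moves(length(moves), nrow(puzzle$pairs), hint_pairs = hints)
  subpaths <- list()
  for (mv in moves) {
    idx <- rdp_simplify(mv$events$x_px, mv$events$y_px, rdp_epsilon)
    subpaths <- c(subpaths, segment_subpaths(mv, idx))
  }
  mve <- mean_velocity(subpaths, mve_weighting)
  mdc <- movement_direction_changes(subpaths)
  data.frame(tst_s = as.numeric(tst), met_s = met, mpt_s = mpt,
             false_moves = cls$false_count, excess_moves = exc,
             hints = hints, mve_px_s = mve, mdc = mdc$mdc,
             mdc_orth = mdc$orthogonal, n_moves = length(moves),
             solved = TRUE)
}

#' Aggregate level metrics over a session
#'
#' Median, IQR and SD per measure across solved levels (nonparametric
#' aggregation, matching the rank-based group analysis).
#'
#' @param level_metrics Data frame of rows from [compute_level_metrics()].
#' @return Data frame with one row per measure: `measure`, `median`,
#'   `iqr`, `sd`, `n_levels`.
#' @export
summarize_session <- function(level_metrics) {
  lm <- level_metrics[isTRUE_vec(level_metrics$solved), , drop = FALSE]
  if (!nrow(lm)) stop("no solved level in session")
  measures <- c("tst_s", "met_s", "mpt_s", "false_moves", "excess_moves",
                "hints", "mve_px_s", "mdc")
  do.call(rbind, lapply(measures, function(m) {
    v <- lm[[m]]
    v <- v[!is.na(v)]
    data.frame(measure = m, median = median(v),
               iqr = unname(diff(quantile(v, c(0.25, 0.75)))),
               sd = if (length(v) > 1L) sd(v) else 0,
               n_levels = length(v))
  }))
}

isTRUE_vec <- function(x) !is.na(x) & x
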