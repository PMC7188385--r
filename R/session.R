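# ---------------------------------------------------------------------------
# Per-level session files: the time-stamped touch-event stream and the
# board-state snapshot stream, plus segmentation of raw events into drag
# moves and the pixel -> cell mapping.
#
# Timestamps are integer milliseconds; durations are reported in seconds.
# The pixel origin is top-left with y increasing downwards; board cells are
# half-open pixel rectangles [origin + i * size, origin + (i + 1) * size).
# ---------------------------------------------------------------------------

EVENT_KINDS <- c("down", "move", "up", "hint", "solved")

#' Board-to-screen geometry
#'
#' @param origin_x,origin_y Top-left corner of the board, pixels.
#' @param cell_size Cell edge length, pixels (> 0).
#' @param screen_width,screen_height Screen size, pixels (defaults match a
#'   12.9-inch tablet in landscape).
#' @return An `nl_geometry` list.
#' @export
board_geometry <- function(origin_x = 100, origin_y = 100, cell_size = 100,
                           screen_width = 2732, screen_height = 2048) {
  stopifnot(cell_size > 0, screen_width > 0, screen_height > 0)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, screen_width = screen_width,
                 screen_height = screen_height),
            class = "nl_geometry")
}

check_geometry_fits <- function(geometry, board) {
  if (geometry$origin_x + board$width * geometry$cell_size > geometry$screen_width ||
      geometry$origin_y + board$height * geometry$cell_size > geometry$screen_height)
    stop("board does not fit on screen under this geometry")
  invisible(TRUE)
}

#' Read / write a touch-event log
#'
#' Delimited text with header `t_ms,x_px,y_px,kind`, one event per line;
#' kinds are `down`, `move`, `up`, `hint`, `solved`.  Events are returned
#' sorted by time; non-monotone input is stably sorted with a warning.
#'
#' @param path File path (or, for `read_touch_log`, a character vector of
#'   log lines).
#' @return Data frame with columns `t_ms` (integer ms), `x_px`, `y_px`,
#'   `kind`.
#' @export
read_touch_log <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (!length(lines) || lines[1] != "t_ms,x_px,y_px,kind")
    stop("touch log must start with header 't_ms,x_px,y_px,kind'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 4L))
    stop(sprintf("malformed touch log line %d: '%s'",
                 which(nf != 4L)[1] + 1L, body[nf != 4L][1]))
  df <- data.frame(
    t_ms = as.integer(vapply(parts, `[`, "", 1L)),
    x_px = as.numeric(vapply(parts, `[`, "", 2L)),
    y_px = as.numeric(vapply(parts, `[`, "", 3L)),
    kind = vapply(parts, `[`, "", 4L))
  bad <- which(is.na(df$t_ms) | !(df$kind %in% EVENT_KINDS) |
                 (is.na(df$x_px) & df$kind %in% c("down", "move", "up")))
  if (length(bad))
    stop(sprintf("malformed touch log line %d", bad[1] + 1L))
  if (is.unsorted(df$t_ms)) {
    warning("touch log timestamps are not monotone; applying stable sort")
    df <- df[order(df$t_ms), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname read_touch_log
#' @param events Touch-event data frame.
#' @export
write_touch_log <- function(events, path) {
  fmt_xy <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE,
                                                    scientific = FALSE))
  lines <- c("t_ms,x_px,y_px,kind",
             sprintf("%d,%s,%s,%s", events$t_ms, fmt_xy(events$x_px),
                     fmt_xy(events$y_px), events$kind))
  writeLines(lines, path)
  invisible(path)
}

#' Segment a touch-event stream into drag moves
#'
#' A move is the sequence of touch points between a touch-down and the
#' matching release; its duration is the down-to-release time in seconds.
#' Move-kind events outside any down-up span are discarded with a warning
#' (sensor noise); an unmatched trailing down is dropped with a warning
#' (unfinished drag); an `up` without a preceding `down` is an error.
#'
#' @param events Touch-event data frame (time-sorted).
#' @return List of `nl_move` objects: lists with `events` (the down..up
#'   rows) and `duration` (seconds).
#' @export
segment_moves <- function(events) {
  stopifnot(is.data.frame(events))
  if (is.unsorted(events$t_ms)) stop("events must be time-sorted")
  moves <- list()
  open_start <- NA_integer_
  stray <- 0L
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k == "down") {
      if (!is.na(open_start)) stop(sprintf(
        "touch down at %d ms inside an open drag", events$t_ms[i]))
      open_start <- i
    } else if (k == "up") {
      if (is.na(open_start))
        stop(sprintf("touch release at %d ms without a preceding touch down",
                     events$t_ms[i]))
      span <- events[open_start:i, , drop = FALSE]
      span <- span[span$kind %in% c("down", "move", "up"), , drop = FALSE]
      moves[[length(moves) + 1L]] <- structure(
        list(events = span,
             duration = (events$t_ms[i] - events$t_ms[open_start]) / 1000),
        class = "nl_move")
      open_start <- NA_integer_
    } else if (k == "move" && is.na(open_start)) {
      stray <- stray + 1L
    }
  }
  if (stray > 0L)
    warning(sprintf("%d move event(s) outside any drag discarded as noise",
                    stray))
  if (!is.na(open_start))
    warning("unmatched touch down at end of log; unfinished drag dropped")
  moves
}

#' @export
print.nl_move <- function(x, ...) {
  cat(sprintf("<nl_move %d samples, %.3f s>\n", nrow(x$events), x$duration))
  invisible(x)
}

#' Map touch coordinates to a board cell
#'
#' Half-open cells: a point on the right or bottom edge of the board is
#' off-board.
#'
#' @param x,y Pixel coordinates (vectorized).
#' @param geometry A [board_geometry()].
#' @param board An [nl_board()].
#' @return Data frame with columns `col`, `row`; `NA` rows mark off-board
#'   points.
#' @export
map_touch_to_cell <- function(x, y, geometry, board) {
  col <- floor((x - geometry$origin_x) / geometry$cell_size)
  row <- floor((y - geometry$origin_y) / geometry$cell_size)
  off <- col < 0 | col >= board$width | row < 0 | row >= board$height
  col[off] <- NA_integer_; row[off] <- NA_integer_
  data.frame(col = as.integer(col), row = as.integer(row))
}

# ---------------------------------------------------------------------------
# Board-state snapshots
# ---------------------------------------------------------------------------

#' Read / write board-state snapshots
#'
#' Delimited text with one record per state change: header
#' `t_ms,c0,c1,...` then per line the timestamp and the row-major cell
#' states (`0` for empty, the pair label for a dot or path cell).
#'
#' @param path File path (or a character vector of lines).
#' @param board An [nl_board()]; record width is checked against it.
#' @return List of `nl_snapshot`s: lists with `t_ms` and `cells` (a
#'   `height x width` character matrix).
#' @export
read_snapshots <- function(path, board) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (!length(lines)) stop("empty snapshot stream")
  n <- board$width * board$height
  header <- paste(c("t_ms", paste0("c", seq_len(n) - 1L)), collapse = ",")
  if (lines[1] != header)
    stop("snapshot record width does not match the board dimensions")
  body <- lines[-1]
  body <- body[nzchar(body)]
  snaps <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(f) != n + 1L)
      stop(sprintf("snapshot line %d has %d cells, expected %d",
                   i + 1L, length(f) - 1L, n))
    structure(list(t_ms = as.integer(f[1]),
                   cells = matrix(f[-1], nrow = board$height,
                                  ncol = board$width, byrow = TRUE)),
              class = "nl_snapshot")
  })
  snaps[order(vapply(snaps, `[[`, integer(1), "t_ms"))]
}

#' @rdname read_snapshots
#' @param snapshots List of `nl_snapshot`s.
#' @export
write_snapshots <- function(snapshots, path) {
  n <- length(snapshots[[1]]$cells)
  lines <- c(paste(c("t_ms", paste0("c", seq_len(n) - 1L)), collapse = ","),
             vapply(snapshots, function(s)
               paste(c(s$t_ms, as.vector(t(s$cells))), collapse = ","),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Initial snapshot of a puzzle
#'
#' Dot cells carry their pair label, all other cells are `"0"`.
#'
#' @param puzzle An [nl_puzzle()].
#' @param t_ms Timestamp (default 0).
#' @return An `nl_snapshot`.
#' @export
initial_snapshot <- function(puzzle, t_ms = 0L) {
  cells <- matrix("0", nrow = puzzle$board$height, ncol = puzzle$board$width)
  pr <- puzzle$pairs
  for (i in seq_len(nrow(pr))) {
    cells[pr$ay[i] + 1L, pr$ax[i] + 1L] <- pr$label[i]
    cells[pr$by[i] + 1L, pr$bx[i] + 1L] <- pr$label[i]
  }
  structure(list(t_ms = as.integer(t_ms), cells = cells),
            class = "nl_snapshot")
}

#' Cell labeling of a reference solution
#'
#' @param puzzle An [nl_puzzle()] with a reference solution.
#' @return `height x width` character matrix with every cell labeled by
#'   the path covering it.
#' @export
solution_labeling <- function(puzzle) {
  stopifnot(!is.null(puzzle$solution))
  cells <- matrix("0", nrow = puzzle$board$height, ncol = puzzle$board$width)
  for (lb in names(puzzle$solution)) {
    p <- puzzle$solution[[lb]]
    cells[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- lb
  }
  cells
}
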