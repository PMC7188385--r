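#' @useDynLib numberlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif rpois rlnorm sd cor pnorm
#'   pchisq pt qnorm setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain types.
#
# Coordinates are 0-based (col, row), origin at the top-left of the board,
# rows increasing downwards.  A grid path is an integer matrix with columns
# `col` and `row`, one cell per row of the matrix, consecutive cells being
# 4-neighbours.  A puzzle holds the board, the dot pairs (path endpoints)
# and, optionally, the reference solution produced by the generator.
# ---------------------------------------------------------------------------

#' Construct a puzzle board
#'
#' @param width,height Board dimensions in cells; both must be at least 2
#'   (graded difficulty levels use 4--8).
#' @return An object of class `nl_board`.
#' @export
nl_board <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(length(width) == 1L, length(height) == 1L,
            !is.na(width), !is.na(height), width >= 2L, height >= 2L)
  structure(list(width = width, height = height), class = "nl_board")
}

#' @export
print.nl_board <- function(x, ...) {
  cat(sprintf("<nl_board %d x %d>\n", x$width, x$height))
  invisible(x)
}

as_path_matrix <- function(cells) {
  m <- as.matrix(cells)
  storage.mode(m) <- "integer"
  colnames(m) <- c("col", "row")
  m
}

#' Construct a Numberlink puzzle
#'
#' @param board An [nl_board()].
#' @param pairs A data frame with columns `label`, `ax`, `ay`, `bx`, `by`
#'   giving, per dot pair, the label (single character) and the 0-based
#'   coordinates of its two dots.
#' @param solution Optional named list of grid paths (integer matrices with
#'   columns `col`, `row`), one per pair, the reference full-cover solution.
#' @return An object of class `nl_puzzle`.
#' @export
nl_puzzle <- function(board, pairs, solution = NULL) {
  stopifnot(inherits(board, "nl_board"), is.data.frame(pairs))
  stopifnot(all(c("label", "ax", "ay", "bx", "by") %in% names(pairs)))
  pairs$label <- as.character(pairs$label)
  if (anyDuplicated(pairs$label))
    stop("dot pair labels must be unique within a puzzle")
  if (any(pairs$ax == pairs$bx & pairs$ay == pairs$by))
    stop("the two dots of a pair must be distinct cells")
  coords <- rbind(cbind(pairs$ax, pairs$ay), cbind(pairs$bx, pairs$by))
  if (any(coords[, 1] < 0 | coords[, 1] >= board$width |
          coords[, 2] < 0 | coords[, 2] >= board$height))
    stop("dot coordinates outside the board")
  if (!is.null(solution)) {
    stopifnot(is.list(solution), length(solution) == nrow(pairs))
    solution <- lapply(solution, as_path_matrix)
    if (is.null(names(solution)) || !setequal(names(solution), pairs$label))
      stop("solution paths must be named by pair label")
  }
  structure(list(board = board, pairs = pairs, solution = solution),
            class = "nl_puzzle")
}

#' @export
print.nl_puzzle <- function(x, ...) {
  cat(sprintf("<nl_puzzle %d x %d, %d pairs%s>\n", x$board$width,
              x$board$height, nrow(x$pairs),
              if (is.null(x$solution)) "" else ", with reference solution"))
  cat(write_grid_text(x), sep = "\n")
  invisible(x)
}

cell_key <- function(col, row, width) row * width + col

# ---------------------------------------------------------------------------
# Rule validation
# ---------------------------------------------------------------------------

#' Validate a candidate Numberlink solution
#'
#' Checks a set of paths against the game rules: each pair of dots must be
#' connected by exactly one continuous path whose endpoints are the dots;
#' steps are horizontal or vertical only; a path visits no cell twice and
#' passes through at least one empty cell; paths may not share cells or
#' cross another pair's dots; and every board cell must be covered once all
#' pairs are connected.
#'
#' @param puzzle An [nl_puzzle()].
#' @param paths Named list of grid paths (matrices with columns `col`,
#'   `row`), names being pair labels.
#' @return An `nl_validation` list with elements `valid` (flag) and
#'   `violations` (data frame with columns `rule`, `label`, `detail`).
#'   `valid` is `TRUE` iff `violations` has zero rows.  Rule identifiers:
#'   `unknown-label`, `endpoint-mismatch`, `non-orthogonal-step`,
#'   `revisited-cell`, `path-too-short`, `crossing`, `uncovered-cell`,
#'   `missing-path`.
#' @export
validate_solution <- function(puzzle, paths) {
  stopifnot(inherits(puzzle, "nl_puzzle"))
  w <- puzzle$board$width; h <- puzzle$board$height
  viol <- list()
  add <- function(rule, label, detail)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, label = label,
                                             detail = detail)
  if (length(paths) && (is.null(names(paths)) || any(names(paths) == "")))
    stop("paths must be a named list (names = pair labels)")

  labels <- puzzle$pairs$label
  for (lb in setdiff(names(paths), labels))
    add("unknown-label", lb, "no dot pair with this label")
  for (lb in setdiff(labels, names(paths)))
    add("missing-path", lb, "pair not connected by any path")

  dot_cells <- cell_key(c(puzzle$pairs$ax, puzzle$pairs$bx),
                        c(puzzle$pairs$ay, puzzle$pairs$by), w)
  dot_owner <- rep(labels, 2L)
  occupied <- integer(0)
  occupied_by <- character(0)

  for (lb in intersect(names(paths), labels)) {
    p <- as_path_matrix(paths[[lb]])
    n <- nrow(p)
    if (n < 3L)
      add("path-too-short", lb,
          sprintf("%d cells; a path must pass through at least one empty cell", n))
    if (any(p[, 1] < 0 | p[, 1] >= w | p[, 2] < 0 | p[, 2] >= h)) {
      add("crossing", lb, "path leaves the board")
      next
    }
    pr <- puzzle$pairs[puzzle$pairs$label == lb, ]
    ends_ok <- (p[1, 1] == pr$ax && p[1, 2] == pr$ay &&
                p[n, 1] == pr$bx && p[n, 2] == pr$by) ||
               (p[1, 1] == pr$bx && p[1, 2] == pr$by &&
                p[n, 1] == pr$ax && p[n, 2] == pr$ay)
    if (!ends_ok)
      add("endpoint-mismatch", lb, "path endpoints are not the pair's dots")
    if (n >= 2L) {
      d <- abs(diff(p))
      if (any(d[, 1] + d[, 2] != 1L))
        add("non-orthogonal-step", lb,
            "consecutive cells must be horizontal/vertical 4-neighbours")
    }
    keys <- cell_key(p[, 1], p[, 2], w)
    if (anyDuplicated(keys))
      add("revisited-cell", lb, "path visits a cell twice")
    # interior cells may not sit on another pair's dot
    interior <- keys[-c(1L, n)]
    bad_dot <- interior %in% dot_cells[dot_owner != lb]
    if (n > 2L && any(bad_dot))
      add("crossing", lb, "path passes through another pair's dot")
    clash <- keys %in% occupied
    if (any(clash)) {
      other <- unique(occupied_by[match(keys[clash], occupied)])
      add("crossing", lb,
          sprintf("shares cells with path(s) %s", paste(other, collapse = ",")))
    }
    occupied <- c(occupied, keys)
    occupied_by <- c(occupied_by, rep(lb, length(keys)))
  }

  all_cells <- seq_len(w * h) - 1L
  uncovered <- setdiff(all_cells, occupied)
  for (k in uncovered)
    add("uncovered-cell", NA_character_,
        sprintf("cell (%d,%d) not covered", k %% w, k %/% w))

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(0), label = character(0), detail = character(0))
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "nl_validation")
}

#' @export
print.nl_validation <- function(x, ...) {
  if (x$valid) cat("<nl_validation> valid solution\n")
  else {
    cat(sprintf("<nl_validation> INVALID: %d violation(s)\n",
                nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Path geometry
# ---------------------------------------------------------------------------

#' Count the turns of a grid path
#'
#' A turn is an interior cell at which the step direction changes between
#' horizontal and vertical (a direction change of the path to the left or
#' right).
#'
#' @param path Grid path matrix (columns `col`, `row`).
#' @return Integer turn count.
#' @export
count_turns <- function(path) {
  p <- as_path_matrix(path)
  if (nrow(p) < 2L) stop("path has fewer than 2 cells: no direction defined")
  d <- diff(p)
  horiz <- d[, 1] != 0L
  sum(horiz[-1] != horiz[-length(horiz)])
}

#' City-block distance between the dots of a pair
#'
#' @param pair One-row data frame with columns `ax`, `ay`, `bx`, `by`
#'   (as in `nl_puzzle()$pairs`).
#' @return `|bx - ax| + |by - ay|` in cells.
#' @export
city_block_distance <- function(pair) {
  abs(pair$bx - pair$ax) + abs(pair$by - pair$ay)
}

#' Mean city-block distance over the pairs of a puzzle
#'
#' One of the four difficulty-governing characteristics of a Numberlink
#' board (alongside size, path count and turn count).
#'
#' @param puzzle An [nl_puzzle()].
#' @return Mean city-block distance across dot pairs.
#' @export
mean_city_block <- function(puzzle) {
  mean(city_block_distance(puzzle$pairs))
}

# ---------------------------------------------------------------------------
# Exhaustive solver (testing oracle)
# ---------------------------------------------------------------------------

#' Enumerate all solutions of a puzzle by exhaustive backtracking
#'
#' Testing oracle: enumerates every full-cover solution by depth-first
#' assignment of paths to pairs.  Exponential; refuses boards larger than
#' `max_board_cells`.
#'
#' @param puzzle An [nl_puzzle()].
#' @param max_board_cells Refusal limit on `width * height` (default 25).
#' @param max_solutions Stop after this many solutions (default 100000).
#' @return List of solutions; each solution is a named list of grid paths
#'   (one per pair, running dot `a` to dot `b`).
#' @export
solve_brute_force <- function(puzzle, max_board_cells = 25L,
                              max_solutions = 100000L) {
  stopifnot(inherits(puzzle, "nl_puzzle"))
  w <- puzzle$board$width; h <- puzzle$board$height
  if (w * h > max_board_cells)
    stop(sprintf("board has %d cells, above the solver limit of %d",
                 w * h, max_board_cells))
  pr <- puzzle$pairs
  dots <- cbind(pr$ax, pr$ay, pr$bx, pr$by)
  storage.mode(dots) <- "integer"
  raw <- nl_solve_cpp(w, h, dots, as.integer(max_solutions))
  lapply(raw, function(sol) {
    paths <- lapply(sol, function(keys) {
      m <- cbind(col = keys %% w, row = keys %/% w)
      storage.mode(m) <- "integer"
      m
    })
    names(paths) <- pr$label
    paths
  })
}

# ---------------------------------------------------------------------------
# Text formats
# ---------------------------------------------------------------------------

#' Write a puzzle as a text grid
#'
#' One row of characters per board row: `.` marks an empty cell, a letter
#' marks a dot (each letter appears exactly twice).
#'
#' @param puzzle An [nl_puzzle()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of grid lines (invisibly when written to file).
#' @export
write_grid_text <- function(puzzle, path = NULL) {
  w <- puzzle$board$width; h <- puzzle$board$height
  g <- matrix(".", nrow = h, ncol = w)
  pr <- puzzle$pairs
  for (i in seq_len(nrow(pr))) {
    g[pr$ay[i] + 1L, pr$ax[i] + 1L] <- pr$label[i]
    g[pr$by[i] + 1L, pr$bx[i] + 1L] <- pr$label[i]
  }
  lines <- apply(g, 1L, paste, collapse = "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a puzzle from a text grid
#'
#' @param x Character vector of grid lines, or a file path of length 1
#'   pointing at an existing file.
#' @return An [nl_puzzle()] (without solution).
#' @export
read_grid_text <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty grid")
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged rows: line %d has %d characters, expected %d",
                 which(widths != widths[1])[1], widths[widths != widths[1]][1],
                 widths[1]))
  w <- widths[1]; h <- length(lines)
  chars <- strsplit(lines, "")
  pos <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    ch <- chars[[r]][c]
    if (ch == ".") next
    if (!grepl("^[A-Za-z]$", ch))
      stop(sprintf("unknown character '%s' at line %d, column %d", ch, r, c))
    pos[[ch]] <- rbind(pos[[ch]], c(c - 1L, r - 1L))
  }
  counts <- vapply(pos, nrow, integer(1))
  if (any(counts != 2L)) {
    bad <- names(counts)[counts != 2L][1]
    stop(sprintf("letter '%s' appears %d time(s); dots must come in pairs",
                 bad, counts[[bad]]))
  }
  labels <- sort(names(pos))
  pairs <- do.call(rbind, lapply(labels, function(lb) {
    m <- pos[[lb]]
    data.frame(label = lb, ax = m[1, 1], ay = m[1, 2],
               bx = m[2, 1], by = m[2, 2])
  }))
  nl_puzzle(nl_board(w, h), pairs)
}

#' Write a structured puzzle record
#'
#' Human-readable key--value document holding board, pairs and (when
#' present) the reference solution; the inverse of [read_puzzle_record()].
#'
#' @param puzzle An [nl_puzzle()].
#' @param path Optional file path.
#' @return Character vector of record lines (invisibly when written).
#' @export
write_puzzle_record <- function(puzzle, path = NULL) {
  lines <- c(sprintf("width: %d", puzzle$board$width),
             sprintf("height: %d", puzzle$board$height))
  pr <- puzzle$pairs
  for (i in seq_len(nrow(pr)))
    lines <- c(lines, sprintf("pair %s: %d,%d %d,%d", pr$label[i],
                              pr$ax[i], pr$ay[i], pr$bx[i], pr$by[i]))
  if (!is.null(puzzle$solution)) {
    for (lb in pr$label) {
      p <- puzzle$solution[[lb]]
      lines <- c(lines, sprintf("path %s: %s", lb,
                                paste(sprintf("%d,%d", p[, 1], p[, 2]),
                                      collapse = " ")))
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

parse_cells <- function(txt) {
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  m <- do.call(rbind, lapply(strsplit(toks, ","), as.integer))
  colnames(m) <- c("col", "row")
  m
}

#' Read a structured puzzle record
#'
#' @param x Character vector of record lines, or a path to a record file.
#' @return An [nl_puzzle()], with solution when path lines are present.
#' @export
read_puzzle_record <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([a-z]+) ?([A-Za-z]?): (.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 4L)
  if (length(bad))
    stop(sprintf("malformed record line %d: '%s'", bad[1], lines[bad[1]]))
  keys <- vapply(kv, `[`, "", 2L)
  labs <- vapply(kv, `[`, "", 3L)
  vals <- vapply(kv, `[`, "", 4L)
  w <- as.integer(vals[keys == "width"][1])
  h <- as.integer(vals[keys == "height"][1])
  if (is.na(w) || is.na(h)) stop("record missing width/height")
  pi <- which(keys == "pair")
  pairs <- do.call(rbind, lapply(pi, function(i) {
    m <- parse_cells(vals[i])
    data.frame(label = labs[i], ax = m[1, 1], ay = m[1, 2],
               bx = m[2, 1], by = m[2, 2])
  }))
  si <- which(keys == "path")
  solution <- NULL
  if (length(si)) {
    solution <- lapply(si, function(i) parse_cells(vals[i]))
    names(solution) <- labs[si]
  }
  nl_puzzle(nl_board(w, h), pairs, solution)
}
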