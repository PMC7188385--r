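# ---------------------------------------------------------------------------
# Random full-cover puzzle generation with a prescribed (width, height,
# paths, turns) tuple.
#
# The generator builds a random Hamiltonian path on the board (a serpentine
# base path randomized by "backbite" moves), then cuts it into `n_paths`
# segments of >= 3 cells each.  Cutting next to a corner cell turns that
# corner into a segment endpoint and removes its turn, so the total turn
# count after cutting is controlled exactly: a cut removes 0, 1 or 2 turns
# depending on placement, and a small dynamic program finds a random cut
# placement whose removed-turn total hits the requested target.  Rejection
# sampling over Hamiltonian paths handles targets outside the reach of the
# current path.
# ---------------------------------------------------------------------------

#' Generation configuration
#'
#' @param seed Optional integer seed; when given, generation is
#'   deterministic (the caller's RNG state is saved and restored).
#' @param max_attempts Rejection-sampling cap on Hamiltonian-path attempts
#'   (default 10000).
#' @param solver_check When `TRUE` and the board has at most 25 cells, the
#'   stored solution is cross-checked against the exhaustive solver.
#' @return An `nl_genconfig` list.
#' @export
generation_config <- function(seed = NULL, max_attempts = 10000L,
                              solver_check = FALSE) {
  stopifnot(max_attempts >= 1L)
  structure(list(seed = seed, max_attempts = as.integer(max_attempts),
                 solver_check = isTRUE(solver_check)),
            class = "nl_genconfig")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# serpentine Hamiltonian path, randomized orientation/reflections
snake_path <- function(w, h) {
  by_rows <- runif(1) < 0.5
  if (!by_rows) { tmp <- w; w <- h; h <- tmp }
  cells <- do.call(rbind, lapply(seq_len(h) - 1L, function(r) {
    cols <- if (r %% 2L == 0L) seq_len(w) - 1L else rev(seq_len(w) - 1L)
    cbind(cols, r)
  }))
  if (runif(1) < 0.5) cells[, 1] <- (w - 1L) - cells[, 1]
  if (runif(1) < 0.5) cells[, 2] <- (h - 1L) - cells[, 2]
  if (!by_rows) cells <- cells[, 2:1, drop = FALSE]
  colnames(cells) <- c("col", "row")
  storage.mode(cells) <- "integer"
  cells
}

# one backbite move: reverse a suffix so the path stays Hamiltonian
backbite <- function(path) {
  n <- nrow(path)
  if (runif(1) < 0.5) path <- path[n:1, , drop = FALSE]
  e <- path[n, ]
  adj <- which(abs(path[, 1] - e[1]) + abs(path[, 2] - e[2]) == 1L)
  adj <- adj[adj < n - 1L]
  if (!length(adj)) return(path)
  j <- if (length(adj) == 1L) adj else sample(adj, 1L)
  rbind(path[seq_len(j), , drop = FALSE],
        path[n:(j + 1L), , drop = FALSE])
}

# logical vector: is cell i (1-based) a turn of the path
corner_flags <- function(path) {
  n <- nrow(path)
  fl <- rep(FALSE, n)
  if (n < 3L) return(fl)
  d <- diff(path)
  horiz <- d[, 1] != 0L
  fl[2:(n - 1L)] <- horiz[-1] != horiz[-length(horiz)]
  fl
}

# Choose p-1 cut positions (cut i splits between cells i and i+1, 1-based)
# with segments >= 3 cells and total removed turns exactly `removal`.
# Returns integer vector of cut positions, or NULL when impossible.
choose_cuts <- function(corners, n_cuts, removal) {
  n <- length(corners)
  if (n_cuts == 0L) return(if (removal == 0L) integer(0) else NULL)
  rem_at <- as.integer(corners[seq_len(n - 1L)]) +
            as.integer(corners[seq(2L, n)])       # removal value of cut i
  lo <- 3L; hi <- n - 3L
  if (hi < lo) return(NULL)
  # reach[k, i, r+1]: k cuts placed, last at i, r turns removed so far
  reach <- array(FALSE, dim = c(n_cuts, n - 1L, removal + 1L))
  for (i in lo:hi) {
    r <- rem_at[i]
    if (r <= removal) reach[1L, i, r + 1L] <- TRUE
  }
  # cum[k, i, r+1): any reach[k, j <= i, r+1]
  if (n_cuts > 1L) {
    cum <- reach
    for (i in (lo + 1L):hi)
      cum[1L, i, ] <- cum[1L, i, ] | cum[1L, i - 1L, ]
    for (k in 2L:n_cuts) {
      for (i in lo:hi) {
        if (i - 3L >= lo) {
          r <- rem_at[i]
          if (r <= removal) {
            pr <- seq_len(removal + 1L - r)
            reach[k, i, pr + r] <- cum[k - 1L, i - 3L, pr]
          }
        }
      }
      cum[k, , ] <- reach[k, , ]
      for (i in (lo + 1L):hi)
        cum[k, i, ] <- cum[k, i, ] | cum[k, i - 1L, ]
    }
  }
  ends <- which(reach[n_cuts, , removal + 1L])
  ends <- ends[ends <= hi]
  if (!length(ends)) return(NULL)
  cuts <- integer(n_cuts)
  i <- if (length(ends) == 1L) ends else sample(ends, 1L)
  cuts[n_cuts] <- i
  r <- removal - rem_at[i]
  if (n_cuts > 1L) for (k in (n_cuts - 1L):1L) {
    cand <- which(reach[k, , r + 1L])
    cand <- cand[cand <= i - 3L]
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    cuts[k] <- i
    r <- r - rem_at[i]
  }
  cuts
}

split_path <- function(path, cuts) {
  bounds <- c(0L, sort(cuts), nrow(path))
  lapply(seq_len(length(bounds) - 1L), function(i)
    path[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE])
}

#' Generate a random full-cover Numberlink puzzle
#'
#' Produces a puzzle whose reference solution covers every board cell with
#' exactly `level$n_paths` non-crossing orthogonal paths whose turn counts
#' sum to exactly `level$n_turns`.  Deterministic given `config$seed`.
#'
#' @param level A [difficulty_level()].
#' @param config A [generation_config()].
#' @return An [nl_puzzle()] carrying the reference solution.
#' @export
generate_puzzle <- function(level, config = generation_config()) {
  stopifnot(inherits(level, "nl_level"), inherits(config, "nl_genconfig"))
  with_seed(config$seed, {
    w <- level$width; h <- level$height
    p <- level$n_paths; t <- level$n_turns
    n <- w * h
    if (n < 3L * p)
      stop(sprintf("level (%d,%d,%d,%d): board too small for %d paths of >= 3 cells",
                   w, h, p, t, p))
    max_removal <- 2L * (p - 1L)
    puz <- NULL
    for (attempt in seq_len(config$max_attempts)) {
      path <- snake_path(w, h)
      turns <- count_turns(path)
      # drift the Hamiltonian path until its turn total is cuttable to t
      drift <- 0L
      while ((turns < t || turns > t + max_removal) && drift < 40L * n) {
        path <- backbite(path)
        turns <- count_turns(path)
        drift <- drift + 1L
      }
      # extra randomization that keeps the turn total in the usable window
      extra <- sample(0L:25L, 1L)
      while (extra > 0L) {
        cand <- backbite(path)
        ct <- count_turns(cand)
        if (ct >= t && ct <= t + max_removal) { path <- cand; turns <- ct }
        extra <- extra - 1L
      }
      if (turns < t || turns > t + max_removal) next
      cuts <- choose_cuts(corner_flags(path), p - 1L, turns - t)
      if (is.null(cuts)) next
      segs <- split_path(path, cuts)
      labels <- LETTERS[seq_len(p)]
      segs <- segs[sample.int(p)]
      names(segs) <- labels
      pairs <- do.call(rbind, lapply(labels, function(lb) {
        s <- segs[[lb]]
        data.frame(label = lb, ax = s[1, 1], ay = s[1, 2],
                   bx = s[nrow(s), 1], by = s[nrow(s), 2])
      }))
      puz <- nl_puzzle(nl_board(w, h), pairs, solution = segs)
      break
    }
    if (is.null(puz))
      stop(sprintf(
        "generation failed for level (%d,%d,%d,%d) after %d attempts: %s",
        w, h, p, t, config$max_attempts,
        "parameters may be infeasible for a full cover"))
    stopifnot(validate_solution(puz, puz$solution)$valid)
    if (config$solver_check && n <= 25L) {
      sols <- solve_brute_force(puz)
      if (!any(vapply(sols, solutions_equal, TRUE, b = puz$solution)))
        stop("stored solution not confirmed by exhaustive solver")
    }
    puz
  })
}

# path-set equality up to per-path direction
solutions_equal <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  all(vapply(names(a), function(lb) {
    pa <- a[[lb]]; pb <- b[[lb]]
    nrow(pa) == nrow(pb) &&
      (all(pa == pb) || all(pa == pb[nrow(pb):1, , drop = FALSE]))
  }, TRUE))
}

#' Feasible turn-total range of a level family
#'
#' Lower bound on the total turn count reachable by the full-cover
#' generator for a `(width, height, n_paths)` family: the straightest
#' Hamiltonian path on a `w x h` board is the serpentine with
#' `2 * (min(w, h) - 1)` turns, and each of the `n_paths - 1` cuts can
#' remove at most 2 turns.  Some nominal tuples in the graded difficulty
#' space (for example 4 paths with 4 total turns on an 8 x 8 board) admit
#' no full cover at all; this bound screens them out.
#'
#' @param width,height,n_paths Level family.
#' @return Integer vector `c(min_turns, max_turns)` with
#'   `max_turns = max(width, height)` (the graded-space ceiling).
#' @export
feasible_turn_range <- function(width, height, n_paths) {
  lo <- max(4L, 2L * (min(width, height) - 1L) - 2L * (n_paths - 1L))
  c(lo, max(width, height))
}
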