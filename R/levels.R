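# ---------------------------------------------------------------------------
# Graded difficulty-level space: all (width, height, paths, turns) tuples
# with dimensions 4..8 and both path and turn counts between 4 and the
# larger board dimension; parallel sets A/B; short/medium/long versions;
# screening-based version assignment; difficulty ranking.
# ---------------------------------------------------------------------------

#' Construct a difficulty level
#'
#' @param width,height Board dimensions (4--8 for graded levels).
#' @param n_paths Number of dot pairs, `4 <= n_paths <= max(width, height)`.
#' @param n_turns Total turn count over all solution paths,
#'   `4 <= n_turns <= max(width, height)`; `n_turns = 0` is allowed for the
#'   straight-paths practice level.
#' @return An `nl_level` list.
#' @export
difficulty_level <- function(width, height, n_paths, n_turns) {
  width <- as.integer(width); height <- as.integer(height)
  n_paths <- as.integer(n_paths); n_turns <- as.integer(n_turns)
  mx <- max(width, height)
  stopifnot(width >= 4L, width <= 8L, height >= 4L, height <= 8L,
            n_paths >= 4L, n_paths <= mx,
            n_turns == 0L || (n_turns >= 4L && n_turns <= mx))
  structure(list(width = width, height = height,
                 n_paths = n_paths, n_turns = n_turns),
            class = "nl_level")
}

#' @export
print.nl_level <- function(x, ...) {
  cat(sprintf("<nl_level (%d, %d, %d, %d)>\n",
              x$width, x$height, x$n_paths, x$n_turns))
  invisible(x)
}

#' @export
format.nl_level <- function(x, ...)
  sprintf("(%d,%d,%d,%d)", x$width, x$height, x$n_paths, x$n_turns)

levels_df <- function(levels) {
  do.call(rbind, lapply(levels, function(l)
    data.frame(width = l$width, height = l$height,
               n_paths = l$n_paths, n_turns = l$n_turns)))
}

df_levels <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    difficulty_level(df$width[i], df$height[i], df$n_paths[i], df$n_turns[i]))
}

#' Enumerate the full graded difficulty space
#'
#' All `(width, height, paths, turns)` tuples with
#' `width, height` in 4..8 and `4 <= paths, turns <= max(width, height)`,
#' sorted deterministically by `(width, height, paths, turns)`.
#'
#' @return Data frame with columns `width`, `height`, `n_paths`, `n_turns`.
#' @export
enumerate_level_space <- function() {
  out <- list()
  for (w in 4:8) for (h in 4:8) {
    mx <- max(w, h)
    for (p in 4:mx) for (t in 4:mx)
      out[[length(out) + 1L]] <- data.frame(width = w, height = h,
                                            n_paths = p, n_turns = t)
  }
  df <- do.call(rbind, out)
  df[order(df$width, df$height, df$n_paths, df$n_turns), , drop = FALSE]
}

#' Build the two parallel difficulty-level sets
#'
#' Both sets contain all 15 square `(w, h, p)` families.  For non-square
#' boards the orientation alternates between the sets along the path-count
#' index -- set A starts with the taller-than-wide orientation reversed,
#' i.e. `(5,4,4), (4,5,5), ...` -- so that each set still contains every
#' board size and both sets share identical multisets of `(area, paths)`.
#' One turn total per retained family is drawn seed-deterministically,
#' uniformly over the feasible range (see [feasible_turn_range()]).
#'
#' @param space Level space from [enumerate_level_space()].
#' @param turn_seed Integer seed for the turn draw.
#' @return List with elements `A` and `B`, each an `nl_levelset`.
#' @export
build_parallel_sets <- function(space = enumerate_level_space(),
                                turn_seed = 1L) {
  fam <- unique(space[, c("width", "height", "n_paths")])
  sq <- fam[fam$width == fam$height, , drop = FALSE]
  keep_A <- sq; keep_B <- sq
  dims <- unique(pmin(fam$width, fam$height) + 10L * pmax(fam$width, fam$height))
  for (d in sort(dims)) {
    a <- d %% 10L; b <- d %/% 10L
    if (a == b) next
    for (p in 4:b) {
      j <- p - 4L
      ori_A <- if (j %% 2L == 0L) c(b, a) else c(a, b)
      ori_B <- rev(ori_A)
      keep_A <- rbind(keep_A, data.frame(width = ori_A[1], height = ori_A[2],
                                         n_paths = p))
      keep_B <- rbind(keep_B, data.frame(width = ori_B[1], height = ori_B[2],
                                         n_paths = p))
    }
  }
  # the turn draw is keyed per unordered (board, paths) family so that a
  # family and its transposed counterpart (and hence sets A and B) share
  # the same turn total
  draw <- function(df, seed) {
    df <- df[order(df$width, df$height, df$n_paths), , drop = FALSE]
    df$n_turns <- vapply(seq_len(nrow(df)), function(i) {
      w <- df$width[i]; h <- df$height[i]; p <- df$n_paths[i]
      rng <- feasible_turn_range(w, h, p)
      fam_seed <- (seed %% 20000L) * 100000L +
        min(w, h) * 10000L + max(w, h) * 1000L + p
      vals <- seq(rng[1], rng[2])
      if (length(vals) == 1L) return(as.integer(vals))
      with_seed(fam_seed, as.integer(sample(vals, 1L)))
    }, integer(1))
    rownames(df) <- NULL
    df
  }
  list(A = nl_levelset("A", "full", draw(keep_A, turn_seed), turn_seed),
       B = nl_levelset("B", "full", draw(keep_B, turn_seed), turn_seed))
}

nl_levelset <- function(set_id, version, levels, order_seed = NULL) {
  structure(list(set_id = set_id, version = version,
                 levels = levels, order_seed = order_seed),
            class = "nl_levelset")
}

#' @export
print.nl_levelset <- function(x, ...) {
  cat(sprintf("<nl_levelset %s/%s: %d levels>\n", x$set_id, x$version,
              nrow(x$levels)))
  invisible(x)
}

#' Restrict a full level set to a named version
#'
#' The short version keeps boards with dimensions in `{4,5,6}`, the medium
#' version `{4,...,7}`, the long version `{4,...,8}`; presentation order is
#' then shuffled seed-deterministically (levels are presented in randomized
#' order to avoid learning effects).
#'
#' @param full_set `nl_levelset` from [build_parallel_sets()].
#' @param version `"short"`, `"medium"` or `"long"`.
#' @param order_seed Integer seed for the presentation shuffle.
#' @return An `nl_levelset`; `levels` carries a `rank` column (difficulty
#'   rank, see [rank_difficulty()]) and rows are in presentation order.
#' @export
build_version <- function(full_set, version, order_seed = 1L) {
  stopifnot(inherits(full_set, "nl_levelset"))
  dims <- switch(version,
                 short = 4:6, medium = 4:7, long = 4:8,
                 stop(sprintf("unknown version '%s'", version)))
  lv <- full_set$levels
  lv <- lv[lv$width %in% dims & lv$height %in% dims, , drop = FALSE]
  lv <- rank_difficulty(lv)
  shuffled <- with_seed(order_seed, lv[sample.int(nrow(lv)), , drop = FALSE])
  rownames(shuffled) <- NULL
  nl_levelset(full_set$set_id, version, shuffled, order_seed)
}

#' The fixed three-level practice block
#'
#' Levels `(4,4,4,0)`, `(4,4,4,4)` and `(5,5,5,5)` in fixed order; the
#' first has straight paths only (zero turns).
#'
#' @return An `nl_levelset` with `set_id = "practice"`.
#' @export
build_practice_block <- function() {
  lv <- data.frame(width = c(4L, 4L, 5L), height = c(4L, 4L, 5L),
                   n_paths = c(4L, 4L, 5L), n_turns = c(0L, 4L, 5L))
  nl_levelset("practice", "practice", lv)
}

#' Assign a participant to a level-set version
#'
#' Screening rule on global cognition (MoCA, 0--30) and executive speed
#' (TMT-B, seconds): short when MoCA < 23 or TMT-B > 120 s; long when
#' MoCA > 28 and TMT-B < 120 s; medium otherwise.  The printed criteria
#' are non-exhaustive conjunctions, so they are resolved with ordered
#' precedence short > medium > long, treating the short criteria as a
#' disjunction -- borderline participants get the easier set.
#'
#' @param moca MoCA score in `[0, 30]`.
#' @param tmt_b TMT-B completion time in seconds, `> 0`.
#' @return `"short"`, `"medium"` or `"long"`.
#' @export
assign_version <- function(moca, tmt_b) {
  stopifnot(length(moca) == 1L, length(tmt_b) == 1L,
            is.finite(moca), is.finite(tmt_b))
  if (moca < 0 || moca > 30) stop("moca must be in [0, 30]")
  if (tmt_b <= 0) stop("tmt_b must be positive")
  if (moca < 23 || tmt_b > 120) return("short")
  if (moca > 28 && tmt_b < 120) return("long")
  "medium"
}

#' Rank difficulty levels
#'
#' Levels are ordered by set size (`width * height`) ascending, then by
#' number of paths, with ties broken by turn count and `(width, height)`.
#'
#' @param levels Data frame with columns `width`, `height`, `n_paths`,
#'   `n_turns` (an `nl_levelset$levels`), or a list of
#'   [difficulty_level()]s.
#' @return The data frame sorted by difficulty with a 1-based `rank`
#'   column.
#' @export
rank_difficulty <- function(levels) {
  df <- if (is.data.frame(levels)) levels else levels_df(levels)
  df$rank <- NULL
  area <- df$width * df$height
  o <- order(area, df$n_paths, df$n_turns, df$width, df$height)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Generate the puzzles of a level set
#'
#' One puzzle per level, seed-deterministic: level `i` is generated with
#' seed `seed + i`.
#'
#' @param levelset An `nl_levelset`.
#' @param seed Base integer seed.
#' @param max_attempts Per-level rejection cap.
#' @return List of [nl_puzzle()]s, one per row of `levelset$levels`.
#' @export
generate_levelset_puzzles <- function(levelset, seed = 1L,
                                      max_attempts = 10000L) {
  lv <- levelset$levels
  lapply(seq_len(nrow(lv)), function(i)
    generate_puzzle(difficulty_level(lv$width[i], lv$height[i],
                                     lv$n_paths[i], lv$n_turns[i]),
                    generation_config(seed = seed + i,
                                      max_attempts = max_attempts)))
}
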