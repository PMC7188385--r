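# ---------------------------------------------------------------------------
# Nonparametric comparison pipeline: Kruskal-Wallis omnibus test with tie
# correction, rank-mean multiple-comparison post hoc tests at a familywise
# alpha, Spearman rank correlation, first-order partial Spearman
# correlation controlling for a covariate, and the pooled per-group
# difficulty-vs-solving-time rank correlation.
#
# Ties are handled by average ranks throughout.
# ---------------------------------------------------------------------------

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom.  When all observations are identical the test
#' degenerates to H = 0, p = 1 (not an error).
#'
#' @param samples Named list of numeric vectors (one per group), or a
#'   data frame with columns `value` and `group`.
#' @return An `nl_test` list: `statistic` (H), `df`, `p_value`, `n`,
#'   `groups`.
#' @export
kruskal_wallis <- function(samples) {
  if (is.data.frame(samples))
    samples <- split(samples$value, samples$group)
  stopifnot(length(samples) >= 2L)
  sizes <- lengths(samples)
  if (any(sizes < 1L)) stop("every group needs at least one observation")
  x <- unlist(samples, use.names = FALSE)
  n <- length(x)
  if (n < 3L) stop("need a total of at least 3 observations")
  g <- rep(seq_along(samples), sizes)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (tie_corr == 0) 0 else h / tie_corr
  df <- length(samples) - 1L
  p <- if (h == 0) 1 else pchisq(h, df, lower.tail = FALSE)
  structure(list(statistic = h, df = df, p_value = p, n = n,
                 groups = names(samples) %||% as.character(seq_along(samples)),
                 sizes = unname(sizes), rank_means = unname(rs / sizes),
                 pairwise = NULL),
            class = "nl_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nl_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.2f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Multiple-comparison post hoc test after Kruskal-Wallis
#'
#' Rank-mean comparisons in the Siegel--Castellan style: the observed
#' difference of mean ranks for each pair of groups is compared against a
#' critical difference at familywise level `alpha`
#' (`z = qnorm(1 - alpha / (k (k - 1)))`).  The reported adjusted p value
#' is the normal-tail p multiplied by the number of one-sided family
#' comparisons `k (k - 1)` and capped at 1.
#'
#' @param samples As for [kruskal_wallis()].
#' @param alpha Familywise significance level (default 0.05).
#' @return The `nl_test` from the omnibus run with a `pairwise` data
#'   frame: `group_i`, `group_j`, `obs_diff` (observed rank-mean
#'   difference), `crit_diff`, `p_adj`, `significant`.
#' @export
posthoc_pairwise <- function(samples, alpha = 0.05) {
  if (is.data.frame(samples))
    samples <- split(samples$value, samples$group)
  if (length(samples) < 2L) stop("post hoc comparison needs >= 2 groups")
  omnibus <- kruskal_wallis(samples)
  k <- length(samples)
  n <- omnibus$n
  sizes <- omnibus$sizes
  rm <- omnibus$rank_means
  zcrit <- qnorm(1 - alpha / (k * (k - 1)))
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    se <- sqrt(n * (n + 1) / 12 * (1 / sizes[i] + 1 / sizes[j]))
    obs <- abs(rm[i] - rm[j])
    crit <- zcrit * se
    p_adj <- if (se == 0) 1 else
      min(1, pnorm(obs / se, lower.tail = FALSE) * k * (k - 1))
    rows[[length(rows) + 1L]] <- data.frame(
      group_i = omnibus$groups[i], group_j = omnibus$groups[j],
      obs_diff = obs, crit_diff = crit, p_adj = p_adj,
      significant = obs > crit)
  }
  omnibus$pairwise <- do.call(rbind, rows)
  omnibus$alpha <- alpha
  omnibus
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p value uses the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`; `rho` is `NA` (flagged via
#'   `degenerate = TRUE`) for constant input.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  rho <- cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

spearman_p <- function(rho, n, df = n - 2L) {
  if (is.na(rho) || abs(rho) >= 1) return(if (is.na(rho)) NA_real_ else 0)
  tt <- rho * sqrt(df / (1 - rho^2))
  2 * pt(abs(tt), df, lower.tail = FALSE)
}

#' Partial Spearman correlation controlling for one covariate
#'
#' First-order partial rank correlation
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` on the pairwise
#' Spearman coefficients; the p value uses the t approximation on n - 3
#' degrees of freedom.  A constant covariate falls back to the simple
#' Spearman correlation; a covariate perfectly correlated with `x` or `y`
#' leaves the coefficient undefined (flagged).
#'
#' @param x,y,covariate Numeric vectors of equal length >= 4.
#' @return List with `rho`, `p_value`, `n`, `degenerate`.
#' @export
partial_spearman <- function(x, y, covariate) {
  keep <- complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; z <- covariate[keep]
  n <- length(x)
  stopifnot(n == length(y), n == length(z), n >= 4L)
  if (length(unique(z)) < 2L) {
    out <- spearman_cor(x, y)
    out$note <- "constant covariate: simple Spearman correlation returned"
    return(out)
  }
  rxy <- cor(rank(x), rank(y))
  rxz <- cor(rank(x), rank(z))
  ryz <- cor(rank(y), rank(z))
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  list(rho = rho, p_value = spearman_p(rho, n, df = n - 3L), n = n,
       degenerate = FALSE)
}

#' Difficulty-vs-solving-time correlation per group
#'
#' Spearman correlation between difficulty rank and total solving time,
#' pooled over the participants of each group.  Unsolved levels are
#' excluded; groups with fewer than 3 usable points are skipped with a
#' warning.
#'
#' @param metrics Long data frame with columns `group`, `level_rank`,
#'   `tst_s` (one row per participant x level, as produced by
#'   [simulate_cohort()] or the scoring CLI).
#' @return Data frame with one row per group: `group`, `rho`, `p_value`,
#'   `n`.
#' @export
difficulty_time_correlation <- function(metrics) {
  stopifnot(all(c("group", "level_rank", "tst_s") %in% names(metrics)))
  rows <- list()
  for (g in unique(metrics$group)) {
    sub <- metrics[metrics$group == g & !is.na(metrics$tst_s), , drop = FALSE]
    if (nrow(sub) < 3L) {
      warning(sprintf("group %s has fewer than 3 usable points; skipped", g))
      next
    }
    sc <- spearman_cor(sub$level_rank, sub$tst_s)
    rows[[length(rows) + 1L]] <- data.frame(group = g, rho = sc$rho,
                                            p_value = sc$p_value, n = sc$n)
  }
  do.call(rbind, rows)
}
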