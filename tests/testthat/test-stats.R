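# nonparametric comparison pipeline

test_that("Kruskal-Wallis handles degenerate and clean separation cases", {
  same <- list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2))
  r <- kruskal_wallis(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  sep <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  r2 <- kruskal_wallis(sep)
  expect_equal(r2$df, 2)
  expect_equal(r2$statistic, oracle_kw_h(unlist(sep), rep(1:3, each = 3)))
  # cross-check against the reference implementation
  kt <- stats::kruskal.test(unlist(sep), factor(rep(1:3, each = 3)))
  expect_equal(r2$statistic, unname(kt$statistic))
  expect_equal(r2$p_value, unname(kt$p.value))

  expect_error(kruskal_wallis(list(a = 1:3)), "2")
})

test_that("H agrees with the oracle on every partition of n = 9 (exact permutation)", {
  vals <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.3, 7.0, 8.8, 9.9)
  combos <- utils::combn(9, 3)
  checked <- 0L
  for (i in seq_len(ncol(combos))) {
    g1 <- combos[, i]
    restv <- setdiff(1:9, g1)
    inner <- utils::combn(restv, 3)
    for (j in seq_len(ncol(inner))) {
      g2 <- inner[, j]
      g3 <- setdiff(restv, g2)
      grp <- integer(9); grp[g1] <- 1L; grp[g2] <- 2L; grp[g3] <- 3L
      h_pkg <- kruskal_wallis(split(vals, grp))$statistic
      expect_equal(h_pkg, oracle_kw_h(vals, grp))
      checked <- checked + 1L
    }
  }
  expect_equal(checked, 1680L)
})

test_that("ties are handled by average ranks with tie correction", {
  tied <- list(a = c(1, 1, 2), b = c(2, 3, 3), c = c(4, 4, 5))
  r <- kruskal_wallis(tied)
  kt <- stats::kruskal.test(unlist(tied), factor(rep(1:3, each = 3)))
  expect_equal(r$statistic, unname(kt$statistic))
})

test_that("post hoc pairwise comparisons flag extreme pairs first and are rank-invariant", {
  set.seed(3)
  low <- rnorm(12, 0); mid <- rnorm(12, 1.2); high <- rnorm(12, 3)
  res <- posthoc_pairwise(list(low = low, mid = mid, high = high))
  pw <- res$pairwise
  ext <- pw[pw$group_i == "low" & pw$group_j == "high", ]
  adj <- pw[pw$group_i == "low" & pw$group_j == "mid", ]
  expect_gt(ext$obs_diff, adj$obs_diff)
  expect_true(ext$significant)
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))

  # identical groups: nothing significant
  same <- list(a = c(2, 2, 2, 2), b = c(2, 2, 2, 2), c = c(2, 2, 2, 2))
  expect_false(any(posthoc_pairwise(same)$pairwise$significant))
  expect_error(posthoc_pairwise(list(a = 1:3)), "2")

  # decisions invariant under a monotone transform
  res2 <- posthoc_pairwise(list(low = exp(low), mid = exp(mid),
                                high = exp(high)))
  expect_equal(res2$pairwise$significant, pw$significant)
  expect_equal(res2$statistic, res$statistic)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 7, 1, 8, 0.5)
  sc <- spearman_cor(x, y)
  expect_equal(sc$rho, cor(rank(x), rank(y)))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(sc$rho, unname(ct$estimate))

  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_true(spearman_cor(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("partial Spearman matches the hand-computed closed form", {
  # ranks chosen so r_xy = 0.8, r_xz = 0.8, r_yz = 0.3 exactly
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  z <- c(1, 3, 2, 5, 4)
  ps <- partial_spearman(x, y, z)
  expect_equal(ps$rho, 0.56 / sqrt(0.36 * 0.91))

  # constant covariate falls back to simple Spearman
  fb <- partial_spearman(x, y, rep(2, 5))
  expect_equal(fb$rho, spearman_cor(x, y)$rho)
  expect_match(fb$note, "constant covariate")

  # covariate perfectly correlated with x: undefined, flagged
  und <- partial_spearman(x, y, x)
  expect_true(und$degenerate)
})

test_that("partial Spearman behaves correctly under simulated dependence structures", {
  set.seed(17)
  n <- 200
  # covariate independent of both: partial ~ simple
  z <- rnorm(n); x <- rnorm(n, 0, 1) + 0.8 * rnorm(n)
  y <- 0.6 * x + rnorm(n)
  expect_equal(partial_spearman(x, y, z)$rho, spearman_cor(x, y)$rho,
               tolerance = 0.12)
  # x and y monotone in z with no extra signal: partial ~ 0
  z2 <- rnorm(n)
  x2 <- z2 + 0.3 * rnorm(n)
  y2 <- z2 + 0.3 * rnorm(n)
  expect_lt(abs(partial_spearman(x2, y2, z2)$rho), 0.15)
  expect_gt(spearman_cor(x2, y2)$rho, 0.7)
})

test_that("rank procedures are invariant under strictly monotone transforms", {
  set.seed(23)
  g <- list(a = rexp(8), b = rexp(8) + 0.5, c = rexp(8) + 1)
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) log(v + 1) * 10))$statistic
  expect_equal(h1, h2)
  x <- runif(20); y <- runif(20)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(exp(x), y^3)$rho)
})

test_that("difficulty-time correlation detects a built-in monotone effect", {
  set.seed(31)
  ranks <- rep(1:10, times = 6)
  tst <- 2 + 0.8 * ranks + rnorm(60, 0, 1.5)
  met <- data.frame(group = rep(c("YA", "OA"), each = 30),
                    level_rank = ranks, tst_s = tst)
  out <- difficulty_time_correlation(met)
  expect_equal(nrow(out), 2)
  expect_true(all(out$rho > 0))
  expect_true(all(out$p_value < 0.05))

  # constant TST: degenerate, flagged as NA
  flat <- data.frame(group = "YA", level_rank = 1:10, tst_s = 5)
  expect_true(is.na(difficulty_time_correlation(flat)$rho))

  # shuffled ranks: null correlation on average
  rhos <- replicate(100, {
    difficulty_time_correlation(
      data.frame(group = "g", level_rank = sample(ranks), tst_s = tst))$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)

  # a group with < 3 points is skipped with a warning
  expect_warning(
    difficulty_time_correlation(
      data.frame(group = c("a", "a", "a", "b", "b"),
                 level_rank = c(1, 2, 3, 1, 2),
                 tst_s = c(1, 2, 3, 1, 2))),
    "fewer than 3")
})
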