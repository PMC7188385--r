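# graded difficulty space, parallel sets, versions, assignment, ranking

test_that("level space structure: 25 board sizes, 15 square families, summation total", {
  sp <- enumerate_level_space()
  expect_equal(nrow(unique(sp[, c("width", "height")])), 25)
  sq <- unique(sp[sp$width == sp$height, c("width", "height", "n_paths")])
  expect_equal(nrow(sq), 15)
  # independent direct-summation oracle for the full tuple count
  total <- sum(vapply(1:25, function(i) {
    wh <- unique(sp[, c("width", "height")])[i, ]
    (max(wh$width, wh$height) - 3L)^2
  }, numeric(1)))
  expect_equal(nrow(sp), total)
  expect_false(any(duplicated(sp)))
  expect_true(all(sp$n_paths >= 4 & sp$n_paths <= pmax(sp$width, sp$height)))
  expect_true(all(sp$n_turns >= 4 & sp$n_turns <= pmax(sp$width, sp$height)))
})

test_that("parallel sets share squares, alternate non-square orientations, and cover all combos", {
  sets <- build_parallel_sets(turn_seed = 1)
  A <- sets$A$levels; B <- sets$B$levels
  expect_equal(nrow(A), nrow(B))

  sqA <- A[A$width == A$height, ]
  sqB <- B[B$width == B$height, ]
  expect_equal(sqA, sqB, ignore_attr = TRUE)
  expect_equal(nrow(unique(sqA[, c("width", "height", "n_paths")])), 15)

  # printed alternation: (5,4,4) in A, (4,5,4) in B; (4,5,5) in A
  expect_true(any(A$width == 5 & A$height == 4 & A$n_paths == 4))
  expect_true(any(B$width == 4 & B$height == 5 & B$n_paths == 4))
  expect_true(any(A$width == 4 & A$height == 5 & A$n_paths == 5))
  expect_true(any(A$width == 8 & A$height == 7 & A$n_paths == 8))
  expect_true(any(B$width == 7 & B$height == 8 & B$n_paths == 8))

  # every non-square (board, paths) combo appears exactly once across the
  # two orientations within each set, 80 combos in total over A and B
  nsqA <- A[A$width != A$height, ]
  nsqB <- B[B$width != B$height, ]
  key <- function(df) paste(pmin(df$width, df$height),
                            pmax(df$width, df$height), df$n_paths)
  expect_equal(sort(key(nsqA)), sort(key(nsqB)))
  expect_false(any(duplicated(key(nsqA))))
  expect_equal(nrow(nsqA) + nrow(nsqB), 80)
  # orientations are opposite between the sets
  expect_false(any(paste(nsqA$width, nsqA$height, nsqA$n_paths) %in%
                   paste(nsqB$width, nsqB$height, nsqB$n_paths)))

  # identical multisets of (area, paths); identical turn totals per family
  expect_equal(sort(paste(A$width * A$height, A$n_paths, A$n_turns)),
               sort(paste(B$width * B$height, B$n_paths, B$n_turns)))
  expect_true(all(A$n_turns >= 4 & A$n_turns <= pmax(A$width, A$height)))
})

test_that("versions nest, respect dimension limits, and shuffle reproducibly", {
  sets <- build_parallel_sets(turn_seed = 1)
  sh <- build_version(sets$A, "short", order_seed = 3)
  md <- build_version(sets$A, "medium", order_seed = 3)
  lg <- build_version(sets$A, "long", order_seed = 3)
  keyify <- function(s) paste(s$levels$width, s$levels$height,
                              s$levels$n_paths, s$levels$n_turns)
  expect_true(all(keyify(sh) %in% keyify(md)))
  expect_true(all(keyify(md) %in% keyify(lg)))
  expect_true(all(sh$levels$width <= 6 & sh$levels$height <= 6))
  expect_true(all(md$levels$width <= 7 & md$levels$height <= 7))
  sh2 <- build_version(sets$A, "short", order_seed = 3)
  expect_identical(sh$levels, sh2$levels)
  sh3 <- build_version(sets$A, "short", order_seed = 4)
  expect_false(identical(sh$levels$rank, sh3$levels$rank))
  expect_error(build_version(sets$A, "extended"), "unknown version")
})

test_that("practice block is the fixed three-level sequence", {
  pb <- build_practice_block()
  expect_equal(nrow(pb$levels), 3)
  expect_equal(pb$levels$n_turns[1], 0)
  expect_equal(pb$levels$width, c(4, 4, 5))
  expect_equal(pb$levels$n_paths, c(4, 4, 5))
  expect_equal(pb$levels$n_turns, c(0, 4, 5))
  # all pass the level invariants (turns = 0 exempted)
  for (i in 1:3)
    expect_s3_class(difficulty_level(pb$levels$width[i], pb$levels$height[i],
                                     pb$levels$n_paths[i], pb$levels$n_turns[i]),
                    "nl_level")
})

test_that("version assignment follows the screening rule with short precedence", {
  expect_equal(assign_version(20, 130), "short")
  expect_equal(assign_version(26, 90), "medium")
  expect_equal(assign_version(29, 60), "long")
  expect_equal(assign_version(20, 90), "short")    # low MoCA alone suffices
  expect_equal(assign_version(29, 130), "short")   # slow TMT-B alone suffices
  expect_equal(assign_version(23, 119), "medium")
  expect_error(assign_version(32, 100), "moca")
  expect_error(assign_version(25, -1), "tmt_b")

  # monotonicity: lowering MoCA or raising TMT-B never lengthens the set
  ord <- c(short = 1, medium = 2, long = 3)
  set.seed(5)
  for (i in 1:50) {
    m <- sample(0:30, 1); tb <- runif(1, 20, 300)
    v0 <- ord[[assign_version(m, tb)]]
    if (m > 0) expect_lte(ord[[assign_version(m - 1, tb)]], v0)
    expect_lte(ord[[assign_version(m, tb + 30)]], v0)
  }
})

test_that("difficulty ranking orders by area then paths, matching a sort oracle", {
  lv <- data.frame(width = c(4, 5, 6, 6, 5), height = c(4, 5, 6, 6, 4),
                   n_paths = c(4, 4, 6, 4, 4), n_turns = c(4, 4, 6, 5, 5))
  rk <- rank_difficulty(lv)
  expect_equal(rk$rank, 1:5)
  expect_true(which(rk$width == 4 & rk$height == 4) <
              which(rk$width == 5 & rk$height == 5))
  expect_true(which(rk$n_paths == 4 & rk$width == 6) <
              which(rk$n_paths == 6 & rk$width == 6))
  # oracle: independent order() by (area, paths)
  sets <- build_parallel_sets(turn_seed = 2)
  sh <- build_version(sets$A, "short", order_seed = 1)$levels
  o <- order(sh$width * sh$height, sh$n_paths, sh$n_turns, sh$width, sh$height)
  expect_equal(sh$rank[o], sort(sh$rank))
})
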