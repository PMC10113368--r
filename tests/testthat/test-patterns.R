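test_that("materialize covers exactly the union of selected rows and columns", {
  expect_equal(materialize(factor_pattern(), 3, 3), matrix(0L, 3, 3))

  M <- materialize(factor_pattern(col_set = c(2, 5)), 6, 6)
  expect_equal(M, grid_two_compounds())

  expect_equal(materialize(factor_pattern(row_set = 1:4), 4, 7),
               matrix(1L, 4, 7))

  M <- materialize(factor_pattern(row_set = 2, col_set = 3), 4, 5)
  expect_true(all(M[2, ] == 1L) && all(M[, 3] == 1L))
  expect_equal(sum(M), 5 + 4 - 1)

  expect_error(materialize(factor_pattern(row_set = 5), 4, 4), "bounds")
})

test_that("materialize is monotone in both selection sets", {
  set.seed(71)
  for (rep in 1:20) {
    R <- sample(2:6, 1); C <- sample(2:6, 1)
    rs <- sample.int(R, sample(0:(R - 1), 1))
    cs <- sample.int(C, sample(0:(C - 1), 1))
    small <- materialize(factor_pattern(rs, cs), R, C)
    extra <- setdiff(1:R, rs)
    extra <- extra[sample.int(length(extra), 1)]
    big <- materialize(factor_pattern(c(rs, extra), cs), R, C)
    expect_true(all(big >= small))
  }
})

test_that("pattern distance is the Hamming mismatch count", {
  zero <- binary_profile(matrix(0L, 4, 4))
  expect_equal(pattern_distance(zero, factor_pattern()), 0)

  p6 <- binary_profile(grid_diagonal())
  expect_equal(pattern_distance(p6, factor_pattern()), 6)
  expect_equal(pattern_distance(p6, factor_pattern()), p6$n_significant)

  g <- materialize(factor_pattern(col_set = 2), 3, 3)
  g[1, 2] <- 0L
  expect_equal(pattern_distance(binary_profile(g), factor_pattern(col_set = 2)), 1)

  # bounds: 0 <= d <= R*C and d(null) = n for random cases
  set.seed(5)
  for (rep in 1:25) {
    pr <- rand_profile(4, 5, runif(1))
    pat <- factor_pattern(sample.int(4, sample(0:4, 1)),
                          sample.int(5, sample(0:5, 1)))
    d <- pattern_distance(pr, pat)
    expect_gte(d, 0)
    expect_lte(d, 20)
    expect_equal(pattern_distance(pr, factor_pattern()), pr$n_significant)
  }
})

test_that("profiles reject incomplete or non-binary grids", {
  g <- matrix(0L, 2, 2); g[1, 1] <- NA
  expect_error(binary_profile(g), "complete")
  expect_error(binary_profile(matrix(2L, 2, 2)), "0 or 1")
  expect_error(binary_profile(matrix(0L, 2, 2,
                                     dimnames = list(c("a", "a"), NULL))),
               "unique")
})

test_that("pattern classification follows the row/column sets", {
  expect_equal(classify_pattern(factor_pattern()), "null")
  expect_equal(classify_pattern(factor_pattern(row_set = 3)), "cell_specific")
  expect_equal(classify_pattern(factor_pattern(col_set = 1)), "compound_specific")
  expect_equal(classify_pattern(factor_pattern(row_set = 1, col_set = 2)), "both")
})

test_that("pattern identity is by materialization, not encoding", {
  expect_true(same_materialization(factor_pattern(row_set = 1:3),
                                   factor_pattern(row_set = 1:3, col_set = 1),
                                   3, 4))
  expect_false(same_materialization(factor_pattern(),
                                    factor_pattern(row_set = 1), 2, 2))
  expect_true(same_materialization(factor_pattern(row_set = 1, col_set = 2),
                                   factor_pattern(row_set = 1, col_set = 2),
                                   3, 3))
})

test_that("exhaustive search recovers the worked example optima", {
  f <- exhaustive_optimal(binary_profile(grid_two_compounds()))
  expect_equal(f$distance, 0)
  expect_true(same_materialization(f$pattern, factor_pattern(col_set = c(2, 5)),
                                   6, 6))

  f <- exhaustive_optimal(binary_profile(grid_single_cell_line()))
  expect_equal(f$distance, 1)
  expect_true(same_materialization(f$pattern, factor_pattern(row_set = 4), 6, 6))

  f <- exhaustive_optimal(binary_profile(grid_row_plus_column()))
  expect_equal(f$distance, 3)
  expect_true(same_materialization(f$pattern,
                                   factor_pattern(row_set = 4, col_set = 4),
                                   6, 6))

  f <- exhaustive_optimal(binary_profile(grid_diagonal()))
  expect_equal(f$distance, 6)
  expect_equal(classify_pattern(f$pattern), "null")

  f <- exhaustive_optimal(binary_profile(matrix(0L, 3, 3)))
  expect_equal(f$distance, 0)
  expect_equal(classify_pattern(f$pattern), "null")
})

test_that("exhaustive search agrees with a naive enumeration oracle", {
  set.seed(31)
  for (rep in 1:30) {
    R <- sample(2:4, 1); C <- sample(2:4, 1)
    pr <- rand_profile(R, C, runif(1, 0.1, 0.6))
    expect_equal(exhaustive_optimal(pr)$distance, naive_min_distance(pr$grid))
  }
})

test_that("exhaustive optimum respects the null-pattern upper bound and transpose symmetry", {
  set.seed(13)
  for (rep in 1:20) {
    pr <- rand_profile(5, 4, 0.35)
    f <- exhaustive_optimal(pr)
    expect_lte(f$distance, pr$n_significant)
    ft <- exhaustive_optimal(binary_profile(t(pr$grid)))
    expect_equal(ft$distance, f$distance)
  }
})

test_that("flipping one cell moves the optimal distance by at most 1", {
  set.seed(97)
  for (rep in 1:15) {
    pr <- rand_profile(4, 4, 0.3)
    d0 <- exhaustive_optimal(pr)$distance
    cell <- sample.int(16, 1)
    g <- pr$grid
    g[cell] <- 1L - g[cell]
    d1 <- exhaustive_optimal(binary_profile(g))$distance
    expect_lte(abs(d1 - d0), 1)
  }
})

test_that("ties are counted over distinct materializations and null is never preferred", {
  # 2x2 single cell: distance 1 achieved by null, row, and column patterns
  g <- matrix(0L, 2, 2); g[1, 1] <- 1L
  f <- exhaustive_optimal(binary_profile(g), tie_policy = "deterministic")
  expect_equal(f$distance, 1)
  expect_gt(f$tie_count, 1)
  expect_false(classify_pattern(f$pattern) == "null")

  # same seed reproduces the same random tie choice
  f1 <- exhaustive_optimal(binary_profile(g), seed = 42)
  f2 <- exhaustive_optimal(binary_profile(g), seed = 42)
  expect_identical(f1$pattern, f2$pattern)

  # all-one profile: every all-covering encoding collapses to one materialization
  f <- exhaustive_optimal(binary_profile(matrix(1L, 3, 3)))
  expect_equal(f$distance, 0)
  expect_equal(f$tie_count, 1)

  expect_error(exhaustive_optimal(rand_profile(20, 10), cap = 26),
               "ga_optimize")
})
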