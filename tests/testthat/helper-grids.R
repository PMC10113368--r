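# Worked 6x6 example grids used across the suite.

# Two full compound columns (2 and 5); a perfect compound-specific pattern.
grid_two_compounds <- function() {
  g <- matrix(0L, 6, 6)
  g[, c(2, 5)] <- 1L
  g
}

# Cell line 4 significant for compounds 1..5 only: one mismatch from the
# full-row pattern.
grid_single_cell_line <- function() {
  g <- matrix(0L, 6, 6)
  g[4, 1:5] <- 1L
  g
}

# Union of row 4 and column 4 with cells (4,1), (4,2) cleared and (1,1) set:
# three mismatches from the row-4 + column-4 pattern.
grid_row_plus_column <- function() {
  g <- matrix(0L, 6, 6)
  g[4, ] <- 1L
  g[, 4] <- 1L
  g[4, 1] <- 0L
  g[4, 2] <- 0L
  g[1, 1] <- 1L
  g
}

# Diagonal hits: no factor explains them, best fit is the null pattern.
grid_diagonal <- function() diag(6L)

rand_profile <- function(R, C, p = 0.3, gene_id = "g") {
  binary_profile(matrix(rbinom(R * C, 1, p), R, C), gene_id)
}

# Independent brute-force oracle: loops over every (row subset, col subset)
# pair with expand.grid and scores it through materialize()/Hamming count.
# Deliberately naive; only for tiny grids.
naive_min_distance <- function(grid) {
  R <- nrow(grid); C <- ncol(grid)
  best <- Inf
  row_subsets <- lapply(0:(2^R - 1), function(m) which(bitwAnd(m, 2^(0:(R - 1))) > 0))
  col_subsets <- lapply(0:(2^C - 1), function(m) which(bitwAnd(m, 2^(0:(C - 1))) > 0))
  for (rs in row_subsets) {
    for (cs in col_subsets) {
      M <- matrix(0L, R, C)
      if (length(rs)) M[rs, ] <- 1L
      if (length(cs)) M[, cs] <- 1L
      best <- min(best, sum(abs(grid - M)))
    }
  }
  best
}
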