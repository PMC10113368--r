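# Binary membership matrix of all 2^k subsets of k items, one subset per row.
subset_matrix <- function(k) {
  m <- 2L^k
  M <- matrix(0L, m, max(k, 1L))
  if (k == 0L) return(matrix(0L, 1L, 0L))
  for (b in seq_len(k))
    M[, b] <- rep(rep(c(0L, 1L), each = 2L^(b - 1L)), length.out = m)
  M
}

#' Optimal factor-specific pattern by exhaustive enumeration
#'
#' Enumerates all `2^(R+C)` (row set, column set) pairs and returns a
#' minimum-distance fit. This is the exact reference optimizer; it refuses
#' grids with more than `cap` total rows + columns (use [ga_optimize()]
#' there). Ties are counted over distinct *materializations* — degenerate
#' encodings of the all-one matrix collapse to one — and resolved per
#' `tie_policy`: the null pattern is never preferred when a non-null optimum
#' exists, matching the convention that a random choice is made among
#' non-null optimal patterns.
#'
#' @param profile A [binary_profile()].
#' @param tie_policy `"seeded_random"` (uniform among non-null optima, uses
#'   `seed`) or `"deterministic"` (smallest pattern, then lexicographic).
#' @param seed Seed for random tie resolution.
#' @param cap Maximum allowed R + C (default 26).
#' @return A `PatternFit` with fields `gene_id`, `pattern`, `distance`,
#'   `tie_count` and `tie_policy_used`.
#' @examples
#' g <- matrix(0L, 6, 6); g[, c(2, 5)] <- 1L
#' exhaustive_optimal(binary_profile(g))$distance # 0
#' @export
exhaustive_optimal <- function(profile,
                               tie_policy = c("seeded_random", "deterministic"),
                               seed = 1L, cap = 26L) {
  stopifnot(inherits(profile, "BinaryProfile"))
  tie_policy <- match.arg(tie_policy)
  E <- profile$grid
  R <- nrow(E); C <- ncol(E)
  if (R + C > cap)
    stop("R + C = ", R + C, " exceeds the exhaustive-search cap (", cap,
         "); use ga_optimize() for grids this large")
  n <- sum(E)

  A <- subset_matrix(R)                      # 2^R row subsets
  sizeS <- as.integer(rowSums(A))
  rs <- rowSums(E); cs <- colSums(E)
  rsS <- as.vector(A %*% rs)
  rowterm <- sizeS * C - 2 * rsS             # covered-by-rows minus ones hit
  AE <- A %*% E                              # ones of E under each row subset

  Bfull <- subset_matrix(C)
  sizeT <- as.integer(rowSums(Bfull))
  csT <- as.vector(Bfull %*% cs)
  colterm <- sizeT * R - 2 * csT

  # Chunk over column subsets to bound the 2^R x 2^C distance block.
  block <- max(1L, min(2L^C, floor(2^22 / 2L^R)))
  best <- Inf
  hits_s <- integer(0); hits_t <- integer(0)
  for (start in seq(1L, 2L^C, by = block)) {
    tt <- start:min(start + block - 1L, 2L^C)
    Bt <- Bfull[tt, , drop = FALSE]
    # d(S,T) = rowterm(S) + colterm(T) - |S||T| + 2*cross(S,T) + n
    D <- outer(rowterm, colterm[tt], "+") -
      outer(sizeS, sizeT[tt]) + 2 * (AE %*% t(Bt)) + n
    m <- min(D)
    if (m < best) {
      best <- m
      hits_s <- integer(0); hits_t <- integer(0)
    }
    if (m <= best) {
      idx <- which(D == best, arr.ind = TRUE)
      hits_s <- c(hits_s, idx[, 1L])
      hits_t <- c(hits_t, tt[idx[, 2L]])
    }
  }

  # Deduplicate by materialization: all-covering pairs share one all-one
  # materialization; every other pair is its own materialization.
  degenerate <- sizeS[hits_s] == R | sizeT[hits_t] == C
  keys <- ifelse(degenerate, "ALL", paste(hits_s, hits_t))
  keep <- !duplicated(keys)
  hits_s <- hits_s[keep]; hits_t <- hits_t[keep]
  patterns <- lapply(seq_along(hits_s), function(k) {
    if (sizeS[hits_s[k]] == R || sizeT[hits_t[k]] == C)
      factor_pattern(seq_len(R), seq_len(C))
    else
      factor_pattern(which(A[hits_s[k], ] == 1L),
                     which(Bfull[hits_t[k], ] == 1L))
  })

  chosen <- with_local_seed(seed, resolve_ties(patterns, tie_policy))
  new_pattern_fit(profile$gene_id, chosen, best, length(patterns), tie_policy)
}
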