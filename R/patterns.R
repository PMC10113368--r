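#' Construct a binary expression profile
#'
#' A `BinaryProfile` is one gene's cell-line (rows) by compound (columns) grid
#' of dichotomized differential-expression calls: 1 where the gene responded
#' significantly in that condition, 0 otherwise. The grid must be complete —
#' missing entries are a hard error, because the pattern distance is only
#' defined on fully observed grids.
#'
#' @param grid Matrix with entries in `{0, 1}` (logical matrices are coerced).
#'   Row names are cell-line identifiers, column names compound identifiers;
#'   both optional but must be unique when present.
#' @param gene_id Identifier of the gene the profile belongs to.
#' @return An object of class `BinaryProfile` with fields `gene_id`, `grid`
#'   (integer matrix) and `n_significant` (number of 1 cells).
#' @examples
#' g <- matrix(0L, 3, 3)
#' g[, 2] <- 1L
#' binary_profile(g, "geneA")
#' @export
binary_profile <- function(grid, gene_id = "gene") {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (anyNA(grid))
    stop("`grid` contains missing values; profiles must be complete")
  vals <- as.integer(grid)
  if (!all(vals %in% c(0L, 1L)))
    stop("`grid` entries must all be 0 or 1")
  dn <- dimnames(grid)
  if (!is.null(dn)) {
    for (ax in seq_along(dn)) {
      if (!is.null(dn[[ax]]) && anyDuplicated(dn[[ax]]))
        stop("axis labels must be unique within each axis")
    }
  }
  g <- matrix(vals, nrow(grid), ncol(grid), dimnames = dn)
  structure(
    list(gene_id = gene_id, grid = g, n_significant = sum(g)),
    class = "BinaryProfile"
  )
}

#' @export
print.BinaryProfile <- function(x, ...) {
  cat(sprintf("BinaryProfile '%s': %d x %d grid, n = %d significant cells\n",
              x$gene_id, nrow(x$grid), ncol(x$grid), x$n_significant))
  invisible(x)
}

#' Construct a factor-specific pattern
#'
#' A factor-specific pattern selects a subset of cell-line rows and a subset
#' of compound columns; it materializes to the binary matrix that is 1 on the
#' union of those full rows and columns. The pattern with both sets empty is
#' the *null pattern* (all-zero materialization), meaning no factor explains
#' the profile.
#'
#' @param row_set Integer indices of selected cell-line rows (may be empty).
#' @param col_set Integer indices of selected compound columns (may be empty).
#' @return An object of class `FactorPattern`.
#' @examples
#' factor_pattern(col_set = c(2, 5)) # compound-specific
#' factor_pattern()                  # the null pattern
#' @export
factor_pattern <- function(row_set = integer(0), col_set = integer(0)) {
  chk <- function(x, what) {
    x <- as.integer(x)
    if (anyNA(x) || any(x < 1L)) stop("`", what, "` must be positive indices")
    sort(unique(x))
  }
  structure(
    list(row_set = chk(row_set, "row_set"), col_set = chk(col_set, "col_set")),
    class = "FactorPattern"
  )
}

#' @export
print.FactorPattern <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = ",") else "-"
  cat(sprintf("FactorPattern <%s> rows {%s} cols {%s}\n",
              classify_pattern(x), fmt(x$row_set), fmt(x$col_set)))
  invisible(x)
}

#' Materialize a factor-specific pattern on an R x C grid
#'
#' @param pattern A [factor_pattern()].
#' @param R,C Grid dimensions (cell lines, compounds).
#' @return Integer R x C matrix with 1 exactly where the cell's row is in
#'   `row_set` or its column is in `col_set`.
#' @examples
#' materialize(factor_pattern(col_set = c(2, 5)), 6, 6)
#' @export
materialize <- function(pattern, R, C) {
  stopifnot(inherits(pattern, "FactorPattern"), is_count(R, 1), is_count(C, 1))
  if (any(pattern$row_set > R) || any(pattern$col_set > C))
    stop("pattern indices out of bounds for a ", R, " x ", C, " grid")
  M <- matrix(0L, R, C)
  if (length(pattern$row_set)) M[pattern$row_set, ] <- 1L
  if (length(pattern$col_set)) M[, pattern$col_set] <- 1L
  M
}

#' Pattern distance between a profile and a factor-specific pattern
#'
#' The pattern distance is the Hamming distance — the count of mismatched
#' cells — between the observed binary grid \eqn{E} and the pattern's
#' materialization \eqn{E'}: \eqn{\sum_{ij} |E_{ij} - E'_{ij}|}. The distance
#' to the null pattern always equals the profile's number of significant
#' cells.
#'
#' @param profile A [binary_profile()].
#' @param pattern A [factor_pattern()] within the profile's bounds.
#' @return Non-negative integer distance.
#' @export
pattern_distance <- function(profile, pattern) {
  stopifnot(inherits(profile, "BinaryProfile"))
  M <- materialize(pattern, nrow(profile$grid), ncol(profile$grid))
  sum(abs(profile$grid - M))
}

#' Classify a pattern by which factors it involves
#'
#' @param pattern A [factor_pattern()].
#' @return One of `"null"` (both sets empty), `"cell_specific"` (rows only),
#'   `"compound_specific"` (columns only) or `"both"`.
#' @export
classify_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "FactorPattern"))
  nr <- length(pattern$row_set) > 0L
  nc <- length(pattern$col_set) > 0L
  if (!nr && !nc) "null"
  else if (nr && !nc) "cell_specific"
  else if (!nr && nc) "compound_specific"
  else "both"
}

#' Do two patterns materialize to the same matrix?
#'
#' Pattern identity is defined by materialization, not by the index pair:
#' selecting all rows makes the column set irrelevant, for example.
#'
#' @param a,b [factor_pattern()] objects.
#' @param R,C Grid dimensions.
#' @return Logical scalar.
#' @export
same_materialization <- function(a, b, R, C) {
  identical(materialize(a, R, C), materialize(b, R, C))
}

# Materialization-canonical representative: the all-one matrix has many
# encodings (all rows + anything, anything + all columns); map them to
# (1:R, 1:C). Every other materialization has a unique (row_set, col_set).
canonical_pattern <- function(pattern, R, C) {
  if (length(pattern$row_set) == R || length(pattern$col_set) == C)
    factor_pattern(seq_len(R), seq_len(C))
  else
    pattern
}

# Shared tie resolution for optimizers. `patterns` is a list of canonical
# FactorPatterns all achieving the minimum distance. The null pattern is
# never preferred when a non-null optimum exists; among non-null ties the
# deterministic policy takes the smallest pattern (|rows| + |cols|, then
# lexicographic), while seeded_random draws uniformly using the current RNG.
resolve_ties <- function(patterns, tie_policy = c("seeded_random", "deterministic")) {
  tie_policy <- match.arg(tie_policy)
  nonnull <- Filter(function(p) classify_pattern(p) != "null", patterns)
  cand <- if (length(nonnull)) nonnull else patterns
  if (length(cand) == 1L) return(cand[[1L]])
  if (tie_policy == "deterministic") {
    key <- vapply(cand, function(p) {
      sprintf("%04d|%s|%s", length(p$row_set) + length(p$col_set),
              paste(sprintf("%05d", p$row_set), collapse = ","),
              paste(sprintf("%05d", p$col_set), collapse = ","))
    }, character(1))
    cand[[order(key)[1L]]]
  } else {
    cand[[sample.int(length(cand), 1L)]]
  }
}

new_pattern_fit <- function(gene_id, pattern, distance, tie_count, tie_policy) {
  structure(
    list(gene_id = gene_id, pattern = pattern, distance = as.integer(distance),
         tie_count = as.integer(tie_count), tie_policy_used = tie_policy),
    class = "PatternFit"
  )
}

#' @export
print.PatternFit <- function(x, ...) {
  cat(sprintf("PatternFit '%s': d = %d, ties = %d (%s)\n  ",
              x$gene_id, x$distance, x$tie_count, x$tie_policy_used))
  print(x$pattern)
  invisible(x)
}
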