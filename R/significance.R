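#' Draw a random profile with a fixed number of significant cells
#'
#' Places exactly `n` ones uniformly at random without replacement among the
#' `R * C` cells. Position-shuffling a fixed-n grid is distributionally
#' identical, so this is the permutation-null generator for the group of
#' genes sharing `n`.
#'
#' @param n Number of significant cells, `0 <= n <= R * C`.
#' @param R,C Grid dimensions.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A [binary_profile()].
#' @export
permute_profile <- function(n, R, C, seed = NULL) {
  stopifnot(is_count(n), is_count(R, 1), is_count(C, 1))
  if (n > R * C) stop("`n` cannot exceed R * C = ", R * C)
  draw <- function() {
    g <- matrix(0L, R, C)
    if (n > 0L) g[sample.int(R * C, n)] <- 1L
    binary_profile(g, gene_id = sprintf("perm_n%d", n))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Build the permutation null distribution for one group
#'
#' For the group of genes whose profiles contain `n` significant cells, draws
#' `L` uniform random profiles with exactly `n` ones and records each one's
#' optimal pattern distance. The distribution depends only on
#' `(n, R, C, L, seed, optimizer)` — never on gene identity — so it is built
#' once per group and shared by every gene in it.
#'
#' @inheritParams permute_profile
#' @param L Number of permutations (default 10,000).
#' @param optimizer `"auto"` picks exact enumeration when `R + C <= cap` and
#'   the genetic algorithm otherwise; `"exhaustive"` and `"ga"` force one.
#' @param ga_config [ga_config()] used when the GA optimizer runs (its own
#'   `seed` field is ignored here; `seed` governs the whole build).
#' @param seed Seed for the permutation draws and GA runs.
#' @param cap Exhaustive-search cap used by `"auto"`.
#' @return A `NullDistribution` with fields `n`, `L`, `distances`, `R`, `C`,
#'   `seed` and `optimizer`.
#' @export
build_null_distribution <- function(n, R, C, L = 10000L,
                                    optimizer = c("auto", "exhaustive", "ga"),
                                    ga_config = factorpat::ga_config(),
                                    seed = 1L, cap = 26L) {
  stopifnot(is_count(n), is_count(R, 1), is_count(C, 1))
  if (n > R * C) stop("`n` cannot exceed R * C = ", R * C)
  if (!is_count(L, 1)) stop("`L` must be a positive integer")
  optimizer <- match.arg(optimizer)
  if (optimizer == "auto") optimizer <- if (R + C <= cap) "exhaustive" else "ga"
  cfg <- ga_config
  pmut <- cfg$mutation_prob_per_bit
  if (is.null(pmut)) pmut <- 1 / (R + C)
  distances <- with_local_seed(seed, {
    cpp_null_distances(as.integer(n), as.integer(R), as.integer(C),
                       as.integer(L), optimizer == "ga",
                       cfg$population_size, cfg$max_generations,
                       cfg$crossover_prob, pmut, cfg$tournament_size,
                       cfg$elitism, cfg$stagnation_stop)
  })
  structure(
    list(n = as.integer(n), L = as.integer(L), distances = distances,
         R = as.integer(R), C = as.integer(C), seed = as.integer(seed),
         optimizer = optimizer),
    class = "NullDistribution"
  )
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution n=%d on %dx%d grid, L=%d (%s): median d = %g\n",
              x$n, x$R, x$C, x$L, x$optimizer, stats::median(x$distances)))
  invisible(x)
}

#' Permutation p-value of an observed optimal distance
#'
#' The p-value is the probability that a random profile with the same number
#' of significant cells fits a factor-specific pattern at least as well as
#' the observed one: the fraction of null distances `<= d_obs`. With
#' `pseudocount = TRUE` the estimate is `(1 + count) / (1 + L)`, which avoids
#' exact zeros ahead of multiple-testing correction.
#'
#' @param d_obs Observed optimal pattern distance.
#' @param null A [build_null_distribution()] result for the gene's group.
#' @param pseudocount Add-one smoothing (default `FALSE`).
#' @param n Optional observed group size; if supplied it must match
#'   `null$n`, otherwise a grouping error is raised.
#' @return p-value in (0, 1] (pseudocount) or [0, 1] (plain).
#' @export
permutation_pvalue <- function(d_obs, null, pseudocount = FALSE, n = NULL) {
  stopifnot(inherits(null, "NullDistribution"), is_count(d_obs))
  if (!is.null(n) && n != null$n)
    stop("grouping error: observation has n = ", n,
         " but the null distribution was built for n = ", null$n)
  count <- sum(null$distances <= d_obs)
  if (pseudocount) (1 + count) / (1 + null$L) else count / null$L
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up conversion of p-values to q-values (FDR). Thin wrapper
#' around [stats::p.adjust()] with input validation, kept as the package's
#' single multiple-testing surface.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}

#' Fit patterns and assess their significance for a set of profiles
#'
#' Runs the full statistical stage: finds each gene's optimal factor-specific
#' pattern (exact enumeration when `R + C <= cap`, genetic algorithm
#' otherwise, with per-gene seeds `seed + gene index`), builds one
#' permutation null per distinct group size n, converts distances to
#' p-values, applies Benjamini-Hochberg across all genes, and flags genes
#' significant when `q < alpha` *and* the fitted pattern is non-null.
#'
#' @param profiles List of [binary_profile()] objects sharing one grid shape.
#' @param alpha FDR significance level (default 0.05).
#' @param L Permutations per null distribution (default 10,000).
#' @inheritParams build_null_distribution
#' @param tie_policy Tie resolution passed to the optimizers.
#' @param pseudocount Passed to [permutation_pvalue()].
#' @param null_cache Optional named list of prebuilt `NullDistribution`s
#'   keyed by `as.character(n)` (see [build_null_cache()]); missing groups
#'   are built and added.
#' @return A data.frame with one row per gene: `gene_id`, `n`, `d`, `p`,
#'   `q`, `significant`, `pattern_rows`, `pattern_cols` (";"-joined axis
#'   labels) and `effect_class`. The per-gene `PatternFit`s and the null
#'   cache are attached as attributes `"fits"` and `"nulls"`.
#' @export
run_significance <- function(profiles, alpha = 0.05, L = 10000L,
                             optimizer = c("auto", "exhaustive", "ga"),
                             ga_config = factorpat::ga_config(),
                             tie_policy = c("seeded_random", "deterministic"),
                             pseudocount = FALSE, seed = 1L,
                             null_cache = NULL, cap = 26L) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "BinaryProfile")))
  optimizer <- match.arg(optimizer)
  tie_policy <- match.arg(tie_policy)
  dims <- vapply(profiles, function(p) dim(p$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all profiles must share one grid shape")
  R <- dims[1, 1]; C <- dims[2, 1]
  opt <- if (optimizer == "auto") {
    if (R + C <= cap) "exhaustive" else "ga"
  } else optimizer

  fits <- lapply(seq_along(profiles), function(i) {
    gene_seed <- as.integer(seed + i)
    if (opt == "exhaustive") {
      exhaustive_optimal(profiles[[i]], tie_policy, seed = gene_seed, cap = cap)
    } else {
      cfg <- ga_config; cfg$seed <- gene_seed
      ga_optimize(profiles[[i]], cfg, tie_policy)
    }
  })

  ns <- vapply(profiles, function(p) p$n_significant, integer(1))
  nulls <- if (is.null(null_cache)) list() else null_cache
  for (n in sort(unique(ns))) {
    key <- as.character(n)
    if (is.null(nulls[[key]])) {
      nulls[[key]] <- build_null_distribution(
        n, R, C, L = L, optimizer = opt, ga_config = ga_config,
        seed = as.integer(seed + 1000000L + n), cap = cap)
    } else if (nulls[[key]]$R != R || nulls[[key]]$C != C) {
      stop("grouping error: cached null for n = ", n,
           " was built for a different grid shape")
    }
  }

  d <- vapply(fits, function(f) f$distance, integer(1))
  p <- vapply(seq_along(fits), function(i) {
    permutation_pvalue(d[i], nulls[[as.character(ns[i])]],
                       pseudocount = pseudocount, n = ns[i])
  }, numeric(1))
  q <- bh_adjust(p)
  effect <- vapply(fits, function(f) classify_pattern(f$pattern), character(1))
  significant <- q < alpha & effect != "null"

  rown <- rownames(profiles[[1]]$grid)
  coln <- colnames(profiles[[1]]$grid)
  lab <- function(idx, labels) {
    if (length(idx) == 0L) return("")
    paste(if (is.null(labels)) idx else labels[idx], collapse = ";")
  }
  records <- data.frame(
    gene_id = vapply(fits, function(f) f$gene_id, character(1)),
    n = ns, d = d, p = p, q = q, significant = significant,
    pattern_rows = vapply(fits, function(f) lab(f$pattern$row_set, rown),
                          character(1)),
    pattern_cols = vapply(fits, function(f) lab(f$pattern$col_set, coln),
                          character(1)),
    effect_class = effect,
    stringsAsFactors = FALSE
  )
  attr(records, "fits") <- fits
  attr(records, "nulls") <- nulls
  attr(records, "grid_dim") <- c(R, C)
  attr(records, "alpha") <- alpha
  records
}

#' Precompute a cache of null distributions
#'
#' @param ns Integer vector of group sizes to build.
#' @inheritParams build_null_distribution
#' @return Named list of `NullDistribution`s keyed by `as.character(n)`.
#' @export
build_null_cache <- function(ns, R, C, L = 10000L,
                             optimizer = c("auto", "exhaustive", "ga"),
                             ga_config = factorpat::ga_config(), seed = 1L,
                             cap = 26L) {
  optimizer <- match.arg(optimizer)
  ns <- sort(unique(as.integer(ns)))
  cache <- lapply(ns, function(n) {
    build_null_distribution(n, R, C, L = L, optimizer = optimizer,
                            ga_config = ga_config,
                            seed = as.integer(seed + 1000000L + n), cap = cap)
  })
  names(cache) <- as.character(ns)
  cache
}

#' Serialize / restore a null-distribution cache
#'
#' The cache is written as JSON keyed by group size, carrying `(R, C, n, L,
#' seed, optimizer)` and the full distance multiset, so a long-running build
#' can be reused across pipeline runs.
#'
#' @param cache Named list from [build_null_cache()].
#' @param path File path.
#' @return `read_null_cache()` returns the named list; `write_null_cache()`
#'   returns `path` invisibly.
#' @export
write_null_cache <- function(cache, path) {
  payload <- lapply(cache, function(nd) {
    list(n = nd$n, L = nd$L, R = nd$R, C = nd$C, seed = nd$seed,
         optimizer = nd$optimizer, distances = nd$distances)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null_cache
#' @export
read_null_cache <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cache <- lapply(payload, function(x) {
    structure(
      list(n = as.integer(x$n), L = as.integer(x$L),
           distances = as.integer(x$distances), R = as.integer(x$R),
           C = as.integer(x$C), seed = as.integer(x$seed),
           optimizer = x$optimizer),
      class = "NullDistribution"
    )
  })
  names(cache) <- names(payload)
  cache
}
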