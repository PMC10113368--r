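#' Genetic-algorithm configuration
#'
#' Hyperparameters of the pattern-search genetic algorithm. The chromosome is
#' a bit string of length R + C (row memberships then column memberships) and
#' fitness is the negative pattern distance, so defaults are tuned for grids
#' up to the 70-bit case of 51 cell lines and 19 compounds.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param max_generations Hard generation limit.
#' @param crossover_prob Probability a child is produced by uniform crossover
#'   rather than copied from one parent.
#' @param mutation_prob_per_bit Per-bit flip probability; `NULL` means
#'   `1 / (R + C)`, resolved when the optimizer sees the grid.
#' @param tournament_size Tournament selection size.
#' @param elitism Number of fittest individuals copied unchanged (>= 1 keeps
#'   the best-so-far distance non-increasing).
#' @param stagnation_stop Stop after this many generations without
#'   improvement of the best distance.
#' @param seed RNG seed; the same seed, profile and config reproduce the
#'   identical fit.
#' @return A `GAConfig` object.
#' @export
ga_config <- function(population_size = 100L, max_generations = 500L,
                      crossover_prob = 0.9, mutation_prob_per_bit = NULL,
                      tournament_size = 3L, elitism = 1L,
                      stagnation_stop = 50L, seed = 1L) {
  if (!is_count(population_size, 2)) stop("`population_size` must be >= 2")
  if (!is_count(max_generations, 1)) stop("`max_generations` must be >= 1")
  if (crossover_prob < 0 || crossover_prob > 1)
    stop("`crossover_prob` must be in [0, 1]")
  if (!is.null(mutation_prob_per_bit) &&
      (mutation_prob_per_bit < 0 || mutation_prob_per_bit > 1))
    stop("`mutation_prob_per_bit` must be in [0, 1]")
  if (!is_count(tournament_size, 1)) stop("`tournament_size` must be >= 1")
  if (!is_count(elitism, 0) || elitism >= population_size)
    stop("`elitism` must be a count smaller than `population_size`")
  if (!is_count(stagnation_stop, 1)) stop("`stagnation_stop` must be >= 1")
  structure(
    list(population_size = as.integer(population_size),
         max_generations = as.integer(max_generations),
         crossover_prob = crossover_prob,
         mutation_prob_per_bit = mutation_prob_per_bit,
         tournament_size = as.integer(tournament_size),
         elitism = as.integer(elitism),
         stagnation_stop = as.integer(stagnation_stop),
         seed = as.integer(seed)),
    class = "GAConfig"
  )
}

#' Initial GA population for a profile
#'
#' The population always contains the null chromosome and (as far as
#' `population_size` permits) every single-row and single-column chromosome;
#' the remainder is uniform random. Seeding the null chromosome guarantees
#' the returned distance never exceeds the profile's number of significant
#' cells.
#'
#' @param profile A [binary_profile()].
#' @param config A [ga_config()].
#' @return Integer matrix `population_size` x `(R + C)` of 0/1 memberships.
#' @export
seed_population <- function(profile, config = ga_config()) {
  stopifnot(inherits(profile, "BinaryProfile"), inherits(config, "GAConfig"))
  B <- nrow(profile$grid) + ncol(profile$grid)
  P <- config$population_size
  pop <- matrix(0L, P, B)
  k <- min(B, P - 1L)
  if (k > 0L) pop[cbind(1L + seq_len(k), seq_len(k))] <- 1L
  extra <- P - 1L - k
  if (extra > 0L) {
    pop[(P - extra + 1L):P, ] <- with_local_seed(
      config$seed,
      matrix(as.integer(runif(extra * B) < 0.5), extra, B)
    )
  }
  pop
}

#' Optimal factor-specific pattern by genetic algorithm
#'
#' Runs tournament selection, uniform crossover, per-bit flip mutation and
#' generational replacement with elitism over (row set, column set)
#' chromosomes, stopping at `max_generations` or after `stagnation_stop`
#' generations without improvement. All distinct best-distance
#' materializations encountered during the run are recorded for tie
#' resolution (null never preferred over a non-null optimum).
#'
#' @inheritParams exhaustive_optimal
#' @param config A [ga_config()]; its `seed` makes the run deterministic.
#' @param max_ties Cap on recorded tied materializations.
#' @return A `PatternFit`. `tie_count` is the number of distinct recorded
#'   best-distance materializations (a lower bound if the cap was hit).
#' @examples
#' g <- matrix(0L, 6, 6); g[4, 1:5] <- 1L
#' ga_optimize(binary_profile(g))$distance # 1
#' @export
ga_optimize <- function(profile, config = ga_config(),
                        tie_policy = c("seeded_random", "deterministic"),
                        max_ties = 64L) {
  stopifnot(inherits(profile, "BinaryProfile"))
  if (!inherits(config, "GAConfig")) stop("`config` must be a ga_config()")
  tie_policy <- match.arg(tie_policy)
  R <- nrow(profile$grid); C <- ncol(profile$grid)
  pmut <- config$mutation_prob_per_bit
  if (is.null(pmut)) pmut <- 1 / (R + C)

  res <- with_local_seed(config$seed, {
    raw <- cpp_ga_optimize(profile$grid, config$population_size,
                           config$max_generations, config$crossover_prob,
                           pmut, config$tournament_size, config$elitism,
                           config$stagnation_stop, as.integer(max_ties))
    patterns <- lapply(seq_len(nrow(raw$ties)), function(k) {
      bits <- raw$ties[k, ]
      factor_pattern(which(bits[seq_len(R)] == 1L),
                     which(bits[R + seq_len(C)] == 1L))
    })
    list(distance = raw$distance,
         tie_count = nrow(raw$ties),
         chosen = resolve_ties(patterns, tie_policy))
  })
  new_pattern_fit(profile$gene_id, res$chosen, res$distance, res$tie_count,
                  tie_policy)
}
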