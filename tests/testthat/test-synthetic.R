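test_that("simulation configs are validated", {
  expect_s3_class(simulation_config(), "SimulationConfig")
  expect_error(simulation_config(planted_fraction = 1.5), "planted_fraction")
  expect_error(simulation_config(row_set_size_range = c(2, 1)), "range")
  expect_error(simulation_config(R = 4, row_set_size_range = c(0, 9)), "range")
  expect_error(simulation_config(row_set_size_range = c(0, 0),
                                 col_set_size_range = c(0, 0)),
               "positive size")
})

test_that("generation is deterministic and matches normal tail masses", {
  cfg <- simulation_config(G = 120, R = 6, C = 6, planted_fraction = 0,
                           seed = 12)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$tensor$values, b$tensor$values)

  # background-only: P(|Z| > 2) = 2 * pnorm(-2) ~ 0.0455
  prop <- mean(abs(a$tensor$values) > 2)
  p0 <- 2 * pnorm(-2)
  se <- sqrt(p0 * (1 - p0) / length(a$tensor$values))
  expect_lt(abs(prop - p0), 3 * se)
  expect_true(all(vapply(a$truth, classify_pattern, character(1)) == "null"))

  # planted cells with no drop-out: P(|N(4,1)| > 2) ~ 0.977
  cfg2 <- simulation_config(G = 150, R = 8, C = 6, planted_fraction = 1,
                            row_set_size_range = c(1, 2),
                            col_set_size_range = c(0, 2),
                            signal_mean = 4, flip_noise = 0, seed = 5)
  d2 <- generate_dataset(cfg2)
  inside <- unlist(lapply(seq_along(d2$truth), function(g) {
    M <- materialize(d2$truth[[g]], 8, 6)
    d2$tensor$values[g, , ][M == 1L]
  }))
  p1 <- pnorm(-2, mean = -4) + pnorm(2, mean = -4, lower.tail = FALSE)
  prop1 <- mean(abs(inside) > 2)
  se1 <- sqrt(p1 * (1 - p1) / length(inside))
  expect_lt(abs(prop1 - p1), 3 * se1)
})

test_that("single-factor planting yields pure cell- or compound-specific truths", {
  cfg <- simulation_config(G = 60, R = 10, C = 8, planted_fraction = 1,
                           row_set_size_range = c(1, 1),
                           col_set_size_range = c(1, 1),
                           single_factor_only = TRUE, seed = 8)
  d <- generate_dataset(cfg)
  classes <- vapply(d$truth, classify_pattern, character(1))
  expect_setequal(unique(classes), c("cell_specific", "compound_specific"))
})

test_that("with strong noiseless signal the dichotomized profile equals the truth", {
  cfg <- simulation_config(G = 30, R = 7, C = 5, planted_fraction = 1,
                           row_set_size_range = c(0, 1),
                           col_set_size_range = c(1, 1),
                           signal_mean = 8, flip_noise = 0, seed = 3)
  d <- generate_dataset(cfg)
  profs <- dichotomize(d$tensor)
  agree <- vapply(seq_along(profs), function(g) {
    M <- materialize(d$truth[[g]], 7, 5)
    mean(profs[[g]]$grid == M)
  }, numeric(1))
  # only background false positives (rate ~4.6%) can disagree
  expect_gt(mean(agree), 0.9)
  # the optimum can never fit worse than the planted truth itself
  d0 <- exhaustive_optimal(profs[[1]])$distance
  expect_lte(d0, pattern_distance(profs[[1]], d$truth[[1]]))
})

test_that("fixture files round-trip through the readers", {
  cfg <- simulation_config(G = 10, R = 4, C = 3, planted_fraction = 0.3,
                           seed = 21)
  d <- generate_dataset(cfg)
  for (fmt in c("gct", "tsv")) {
    paths <- write_dataset(d, tempfile("fx"), format = fmt)
    mat <- read_zscore_matrix(paths$matrix)
    meta <- read_signature_metadata(paths$metadata)
    tens <- assemble_tensor(mat, meta, "6 h",
                            cell_lines = dimnames(d$tensor$values)[[2]],
                            compounds = dimnames(d$tensor$values)[[3]])
    expect_equal(tens$values, d$tensor$values, tolerance = 1e-12)
  }
})

test_that("recovery metrics implement the stated conventions", {
  rec <- data.frame(
    gene_id = paste0("g", 1:4),
    n = 1L, d = 0L, p = 0.001, q = 0.004,
    significant = c(TRUE, TRUE, FALSE, FALSE),
    pattern_rows = "", pattern_cols = "1",
    effect_class = "compound_specific", stringsAsFactors = FALSE
  )
  attr(rec, "grid_dim") <- c(3, 3)
  fits <- list(
    structure(list(gene_id = "g1", pattern = factor_pattern(col_set = 1),
                   distance = 0L, tie_count = 1L,
                   tie_policy_used = "deterministic"), class = "PatternFit"),
    structure(list(gene_id = "g2", pattern = factor_pattern(col_set = 2),
                   distance = 0L, tie_count = 1L,
                   tie_policy_used = "deterministic"), class = "PatternFit"),
    NULL, NULL
  )
  attr(rec, "fits") <- fits
  truth <- list(g1 = factor_pattern(col_set = 1),
                g2 = factor_pattern(col_set = 1),  # wrong column recovered
                g3 = factor_pattern(row_set = 2),  # planted but missed
                g4 = factor_pattern())             # true negative
  m <- recovery_metrics(truth, rec)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 1)
  expect_equal(m$exact_recovery, 0.5)

  # empty-set conventions: nothing planted, nothing called
  truth0 <- list(g1 = factor_pattern(), g2 = factor_pattern(),
                 g3 = factor_pattern(), g4 = factor_pattern())
  rec0 <- rec
  rec0$significant <- FALSE
  m0 <- recovery_metrics(truth0, rec0)
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 1)
  expect_equal(m0$exact_recovery, 1)

  expect_error(recovery_metrics(truth[1:3], rec), "align")
})
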