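make_matrix <- function(G = 3, S = 4) {
  set.seed(99)
  m <- matrix(round(rnorm(G * S), 4), G, S,
              dimnames = list(sprintf("gene%02d", 1:G), sprintf("sig%02d", 1:S)))
  m
}

test_that("GCT 1.3 files round-trip through writer and reader", {
  m <- make_matrix()
  path <- tempfile(fileext = ".gct")
  write_zscore_matrix(m, path, "gct")
  back <- read_zscore_matrix(path, "gct")
  expect_equal(back, m)
  expect_identical(rownames(back), rownames(m))

  # malformed header and dimension mismatches are named errors
  bad <- tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t4"), bad)
  expect_error(read_zscore_matrix(bad, "gct"), "#1.3")
  lines <- readLines(path)
  lines[2] <- "5\t4\t0\t0"
  writeLines(lines, bad)
  expect_error(read_zscore_matrix(bad, "gct"), "declared 5")
})

test_that("GCT files with metadata blocks parse the data core", {
  path <- tempfile(fileext = ".gct")
  writeLines(c(
    "#1.3", "2\t2\t1\t1",
    "id\tdesc\ts1\ts2",
    "dose\t\t10\t20",
    "g1\tfoo\t1.5\t-2.25",
    "g2\tbar\t0\t3"
  ), path)
  m <- read_zscore_matrix(path, "gct")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["g2", "s2"], 3)
})

test_that("TSV matrices round-trip and reject duplicate gene ids", {
  m <- make_matrix()
  path <- tempfile(fileext = ".tsv")
  write_zscore_matrix(m, path, "tsv")
  expect_equal(read_zscore_matrix(path, "tsv"), m)

  dup <- m
  rownames(dup) <- c("geneA", "geneA", "geneB")
  path2 <- tempfile(fileext = ".tsv")
  df <- data.frame(id = rownames(dup), dup, check.names = FALSE)
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_zscore_matrix(path2, "tsv"), "duplicate gene ids")
})

test_that("HDF5 matrices round-trip bit-exactly", {
  skip_if_not_installed("rhdf5")
  m <- make_matrix()
  path <- tempfile(fileext = ".h5")
  write_zscore_matrix(m, path, "hdf5")
  expect_equal(read_zscore_matrix(path, "hdf5"), m)
})

test_that("tensor assembly enforces completeness and unambiguity", {
  meta <- data.frame(
    signature_id = c("s1", "s2", "s3", "s4"),
    cell_line = c("A", "A", "B", "B"),
    perturbagen = c("x", "y", "x", "y"),
    dose = "10 uM", time_point = "6 h", stringsAsFactors = FALSE
  )
  m <- matrix(seq_len(8), 2, 4,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  tens <- assemble_tensor(m, meta, "6 h", cell_lines = c("A", "B"),
                          compounds = c("x", "y"))
  expect_s3_class(tens, "ZScoreTensor")
  expect_equal(dim(tens$values), c(2, 2, 2))
  expect_equal(tens$values["g1", "B", "y"], m["g1", "s4"])

  # missing pair is a completeness error naming the pair
  expect_error(assemble_tensor(m, meta[-3, ], "6 h",
                               cell_lines = c("A", "B"),
                               compounds = c("x", "y")),
               "B / x")

  # a second dose for one pair is ambiguous without a dose filter
  meta2 <- rbind(meta, data.frame(signature_id = "s5", cell_line = "A",
                                  perturbagen = "x", dose = "1 uM",
                                  time_point = "6 h"))
  m2 <- cbind(m, s5 = c(9, 10))
  expect_error(assemble_tensor(m2, meta2, "6 h", cell_lines = c("A", "B"),
                               compounds = c("x", "y")),
               "ambiguous")
  tens2 <- assemble_tensor(m2, meta2, "6 h", cell_lines = c("A", "B"),
                           compounds = c("x", "y"),
                           dose_map = c(x = "10 uM", y = "10 uM"))
  expect_equal(tens2$values["g1", "A", "x"], m["g1", "s1"])

  # axis order follows the user-supplied lists
  tens3 <- assemble_tensor(m, meta, "6 h", cell_lines = c("B", "A"),
                           compounds = c("y", "x"))
  expect_equal(dimnames(tens3$values)[[2]], c("B", "A"))
  expect_equal(tens3$values["g1", "B", "y"], tens$values["g1", "B", "y"])
})

test_that("assembly is invariant to metadata row order", {
  meta <- data.frame(
    signature_id = sprintf("s%d", 1:6),
    cell_line = rep(c("A", "B", "C"), each = 2),
    perturbagen = rep(c("x", "y"), 3),
    dose = "d", time_point = "6 h", stringsAsFactors = FALSE
  )
  set.seed(4)
  m <- matrix(rnorm(18), 3, 6,
              dimnames = list(paste0("g", 1:3), meta$signature_id))
  t1 <- assemble_tensor(m, meta, "6 h")
  t2 <- assemble_tensor(m, meta[sample(6), ], "6 h",
                        cell_lines = c("A", "B", "C"),
                        compounds = c("x", "y"))
  expect_equal(t1$values, t2$values)
})

test_that("dichotomization is strict at the threshold and sign-symmetric", {
  vals <- array(c(2.5, 2.0, 1.9, -2.0, -3.1, 0, 2.0001, -1.99),
                dim = c(2, 2, 2),
                dimnames = list(c("g1", "g2"), c("A", "B"), c("x", "y")))
  tens <- structure(list(values = vals, time_point = "6 h", dose_map = NULL),
                    class = "ZScoreTensor")
  profs <- dichotomize(tens)
  expect_equal(profs$g1$grid, matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                     dimnames = list(c("A", "B"), c("x", "y"))))
  expect_equal(profs$g2$grid[1, 1], 0L)  # |Z| = 2 exactly is NOT significant
  expect_equal(profs$g2$n_significant, 0L)

  neg <- tens; neg$values <- -neg$values
  expect_equal(lapply(dichotomize(neg), `[[`, "grid"),
               lapply(profs, `[[`, "grid"))

  tens$values[1] <- NA
  expect_error(dichotomize(tens), "complete")
})
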