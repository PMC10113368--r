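#' Configuration of the synthetic z-score tensor generator
#'
#' The generator emulates a gene x cell-line x compound tensor of level-5
#' style z-scores: background cells draw standard normal noise, and a chosen
#' fraction of genes carries a planted factor-specific pattern whose cells
#' draw `|Z|` centered at `signal_mean` with random sign, except that with
#' probability `flip_noise` a pattern cell falls back to background (a
#' drop-out). Defaults place clearly detectable signal (`signal_mean = 4`,
#' well past the |Z| > 2 dichotomization threshold) with a realistic 5%
#' drop-out.
#'
#' @param G Number of genes.
#' @param R,C Grid dimensions (cell lines, compounds).
#' @param planted_fraction Proportion of genes given a true non-null pattern.
#' @param row_set_size_range,col_set_size_range Length-2 integer ranges for
#'   planted row/column set sizes; either may include 0 to allow pure
#'   compound- or cell-specific truths (a draw of (0, 0) is redrawn on the
#'   axis that permits a positive size).
#' @param single_factor_only If `TRUE`, each planted gene gets exactly one
#'   factor: an axis is chosen uniformly among those whose range allows a
#'   positive size, and the other set stays empty.
#' @param signal_mean Location of `|Z|` inside the pattern (default 4.0).
#' @param flip_noise Probability a pattern cell draws background instead
#'   (default 0.05).
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return A `SimulationConfig` object.
#' @export
simulation_config <- function(G = 200L, R = 8L, C = 5L,
                              planted_fraction = 0.25,
                              row_set_size_range = c(0L, 2L),
                              col_set_size_range = c(0L, 2L),
                              single_factor_only = FALSE,
                              signal_mean = 4.0, flip_noise = 0.05,
                              seed = 1L) {
  if (!is_count(G, 1) || !is_count(R, 1) || !is_count(C, 1))
    stop("`G`, `R`, `C` must be positive integers")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("`planted_fraction` must be in [0, 1]")
  chk_range <- function(r, lim, what) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0 || r[2] > lim)
      stop("`", what, "` must be an increasing integer range within [0, ",
           lim, "]")
    as.integer(r)
  }
  row_set_size_range <- chk_range(row_set_size_range, R, "row_set_size_range")
  col_set_size_range <- chk_range(col_set_size_range, C, "col_set_size_range")
  if (planted_fraction > 0 &&
      row_set_size_range[2] == 0L && col_set_size_range[2] == 0L)
    stop("planted patterns require a positive size on at least one axis")
  if (flip_noise < 0 || flip_noise > 1) stop("`flip_noise` must be in [0, 1]")
  structure(
    list(G = as.integer(G), R = as.integer(R), C = as.integer(C),
         planted_fraction = planted_fraction,
         row_set_size_range = row_set_size_range,
         col_set_size_range = col_set_size_range,
         single_factor_only = isTRUE(single_factor_only),
         signal_mean = signal_mean, flip_noise = flip_noise,
         seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Generate a synthetic tensor with planted factor-specific patterns
#'
#' @param config A [simulation_config()].
#' @return List with `tensor` (a `ZScoreTensor` with gene ids `gene_0001`...,
#'   cell lines `CL01`..., compounds `CP01`...) and `truth`, a named list of
#'   the planted [factor_pattern()]s (the null pattern for unplanted genes).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  G <- config$G; R <- config$R; C <- config$C
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  cells <- sprintf("CL%02d", seq_len(R))
  compounds <- sprintf("CP%02d", seq_len(C))

  out <- with_local_seed(config$seed, {
    values <- array(rnorm(G * R * C), dim = c(G, R, C),
                    dimnames = list(gene_ids, cells, compounds))
    n_planted <- round(config$planted_fraction * G)
    planted <- if (n_planted > 0) sample.int(G, n_planted) else integer(0)
    truth <- rep(list(factor_pattern()), G)
    names(truth) <- gene_ids
    draw_size <- function(range) {
      if (range[1] == range[2]) range[1]
      else sample(range[1]:range[2], 1L)
    }
    for (g in planted) {
      if (config$single_factor_only) {
        axes <- c("row", "col")[c(config$row_set_size_range[2] > 0,
                                  config$col_set_size_range[2] > 0)]
        axis <- if (length(axes) == 1L) axes else sample(axes, 1L)
        nr <- if (axis == "row")
          max(1L, draw_size(config$row_set_size_range)) else 0L
        nc <- if (axis == "col")
          max(1L, draw_size(config$col_set_size_range)) else 0L
      } else {
        repeat {
          nr <- draw_size(config$row_set_size_range)
          nc <- draw_size(config$col_set_size_range)
          if (nr + nc > 0L) break
        }
      }
      pat <- factor_pattern(
        if (nr > 0L) sample.int(R, nr) else integer(0),
        if (nc > 0L) sample.int(C, nc) else integer(0)
      )
      truth[[g]] <- pat
      M <- materialize(pat, R, C)
      inside <- which(M == 1L)
      keep <- runif(length(inside)) >= config$flip_noise
      hit <- inside[keep]
      signs <- sample(c(-1, 1), length(hit), replace = TRUE)
      slab <- values[g, , ]
      slab[hit] <- signs * rnorm(length(hit), mean = config$signal_mean, sd = 1)
      values[g, , ] <- slab
    }
    list(values = values, truth = truth)
  })

  tensor <- structure(
    list(values = out$values, time_point = "6 h", dose_map = NULL),
    class = "ZScoreTensor"
  )
  list(tensor = tensor, truth = out$truth)
}

#' Write a synthetic dataset as pipeline-ready fixture files
#'
#' Flattens the tensor into a genes x signatures matrix (one signature per
#' (cell line, compound) pair, ids `CELL:COMPOUND:6h`), writes it in the
#' requested dialect together with the matching signature metadata table and
#' the ground-truth pattern table.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param format Matrix dialect: `"gct"`, `"tsv"` or `"hdf5"`.
#' @return Named list of file paths (`matrix`, `metadata`, `truth`).
#' @export
write_dataset <- function(dataset, dir, format = c("gct", "tsv", "hdf5")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  values <- dataset$tensor$values
  dn <- dimnames(values)
  combos <- expand.grid(cell_line = dn[[2]], perturbagen = dn[[3]],
                        stringsAsFactors = FALSE)
  sig_ids <- paste(combos$cell_line, combos$perturbagen, "6h", sep = ":")
  mat <- matrix(NA_real_, length(dn[[1]]), nrow(combos),
                dimnames = list(dn[[1]], sig_ids))
  for (k in seq_len(nrow(combos)))
    mat[, k] <- values[, combos$cell_line[k], combos$perturbagen[k]]

  ext <- switch(format, gct = "gct", tsv = "tsv", hdf5 = "h5")
  matrix_path <- file.path(dir, paste0("zscores.", ext))
  write_zscore_matrix(mat, matrix_path, format)

  meta <- data.frame(signature_id = sig_ids,
                     cell_line = combos$cell_line,
                     perturbagen = combos$perturbagen,
                     dose = "10 uM", time_point = "6 h",
                     stringsAsFactors = FALSE)
  metadata_path <- file.path(dir, "metadata.tsv")
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  fmt <- function(s) paste(s, collapse = ";")
  truth_df <- data.frame(
    gene_id = names(dataset$truth),
    rows = vapply(dataset$truth, function(p) fmt(p$row_set), character(1)),
    cols = vapply(dataset$truth, function(p) fmt(p$col_set), character(1)),
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(matrix = matrix_path, metadata = metadata_path, truth = truth_path)
}

#' Score pattern recovery against the planted ground truth
#'
#' Detection treats "planted" (non-null truth) as the positive class and
#' "declared significant" as the call. Among true positives it additionally
#' scores exact-materialization recovery: the fitted pattern must
#' materialize to exactly the planted one. Empty denominators report 1 by
#' convention (nothing to miss, nothing called falsely), keeping noise-only
#' calibration runs crash-free.
#'
#' @param truth Named list of planted [factor_pattern()]s from
#'   [generate_dataset()].
#' @param records [run_significance()] output for the same genes.
#' @return List with `precision`, `recall`, `exact_recovery`,
#'   `n_planted`, `n_significant`, `n_true_positive`.
#' @export
recovery_metrics <- function(truth, records) {
  stopifnot(is.data.frame(records))
  if (!setequal(names(truth), records$gene_id))
    stop("gene ids of `truth` and `records` do not align")
  fits <- attr(records, "fits")
  names(fits) <- records$gene_id
  planted <- names(truth)[vapply(truth, function(p)
    classify_pattern(p) != "null", logical(1))]
  called <- records$gene_id[records$significant]
  tp <- intersect(planted, called)
  precision <- if (length(called)) length(tp) / length(called) else 1
  recall <- if (length(planted)) length(tp) / length(planted) else 1
  dims <- attr(records, "grid_dim")
  if (is.null(dims)) stop("`records` lacks the grid_dim attribute")
  exact <- if (length(tp)) {
    mean(vapply(tp, function(g) {
      same_materialization(fits[[g]]$pattern, truth[[g]], dims[1], dims[2])
    }, logical(1)))
  } else 1
  list(precision = precision, recall = recall, exact_recovery = exact,
       n_planted = length(planted), n_significant = length(called),
       n_true_positive = length(tp))
}
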