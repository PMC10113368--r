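#' Read a genes x signatures z-score matrix
#'
#' Supported dialects: GCT 1.3 (versioned `#1.3` header plus dimension line,
#' optional row/column metadata blocks), plain TSV (gene ids in the first
#' column, signature ids in the header), and an HDF5 container with three
#' named datasets (`matrix` stored genes x signatures, `row_ids`,
#' `col_ids`; requires the rhdf5 package).
#'
#' @param path File path.
#' @param format One of `"gct"`, `"tsv"`, `"hdf5"`; default guesses from the
#'   file extension.
#' @return Numeric matrix with gene ids as rownames and signature ids as
#'   colnames, in file order.
#' @export
read_zscore_matrix <- function(path, format = c("auto", "gct", "tsv", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gct = "gct", h5 = "hdf5", hdf5 = "hdf5", "tsv")
  }
  mat <- switch(format,
                gct = read_gct(path),
                tsv = read_tsv_matrix(path),
                hdf5 = read_hdf5_matrix(path))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate signature ids in ", path)
  mat
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.3"))
    stop("malformed GCT header in ", path, ": expected '#1.3' on line 1")
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("malformed GCT dimension line in ", path, " (line 2)")
  nr <- dims[1L]; nc <- dims[2L]
  nrmeta <- if (length(dims) >= 3L && !is.na(dims[3L])) dims[3L] else 0L
  ncmeta <- if (length(dims) >= 4L && !is.na(dims[4L])) dims[4L] else 0L
  header <- strsplit(lines[3L], "\t")[[1]]
  if (length(header) != 1L + nrmeta + nc)
    stop("GCT header row of ", path, " has ", length(header),
         " fields; expected ", 1L + nrmeta + nc, " (line 3)")
  sig_ids <- header[(2L + nrmeta):length(header)]
  data_lines <- lines[(4L + ncmeta):length(lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) != nr)
    stop("GCT body of ", path, " has ", length(data_lines),
         " data rows; dimension line declared ", nr)
  fields <- strsplit(data_lines, "\t")
  bad <- which(lengths(fields) != 1L + nrmeta + nc)
  if (length(bad))
    stop("GCT data row ", bad[1L] + 3L + ncmeta, " of ", path,
         " has the wrong field count")
  gene_ids <- vapply(fields, `[`, character(1), 1L)
  vals <- vapply(fields, function(f)
    as.numeric(f[(2L + nrmeta):(1L + nrmeta + nc)]), numeric(nc))
  mat <- if (nc == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(mat) <- list(gene_ids, sig_ids)
  mat
}

read_tsv_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("TSV matrix ", path, " needs id + value columns")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric values in TSV matrix ", path)
  rownames(mat) <- ids
  mat
}

read_hdf5_matrix <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 support requires the rhdf5 package")
  mat <- rhdf5::h5read(path, "matrix")
  row_ids <- as.character(rhdf5::h5read(path, "row_ids"))
  col_ids <- as.character(rhdf5::h5read(path, "col_ids"))
  if (nrow(mat) != length(row_ids) || ncol(mat) != length(col_ids))
    stop("HDF5 dataset dimensions disagree with id vectors in ", path)
  dimnames(mat) <- list(row_ids, col_ids)
  mat
}

#' Write a z-score matrix
#'
#' Writers matching [read_zscore_matrix()]'s dialects; round-trips are exact
#' for identifiers and value-exact to printed precision (GCT/TSV) or
#' bit-exact (HDF5).
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param format `"gct"`, `"tsv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
write_zscore_matrix <- function(mat, path, format = c("gct", "tsv", "hdf5")) {
  format <- match.arg(format)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.3", paste(nrow(mat), ncol(mat), 0L, 0L, sep = "\t"),
                 paste(c("id", colnames(mat)), collapse = "\t")), con)
    body <- apply(mat, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(rownames(mat), body, sep = "\t"), con)
  } else if (format == "tsv") {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 support requires the rhdf5 package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(unname(mat), path, "matrix")
    rhdf5::h5write(rownames(mat), path, "row_ids")
    rhdf5::h5write(colnames(mat), path, "col_ids")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Read a signature metadata table
#'
#' A delimited table with (at least) the five named columns `signature_id`,
#' `cell_line`, `perturbagen`, `dose`, `time_point`, one row per signature.
#'
#' @param path File path.
#' @return data.frame with the five columns as character.
#' @export
read_signature_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("signature_id", "cell_line", "perturbagen", "dose", "time_point")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$signature_id))
    stop("duplicate signature_id values in ", path)
  df[need] <- lapply(df[need], as.character)
  df
}

#' Assemble the gene x cell-line x compound z-score tensor
#'
#' Selects, for every requested (cell line, compound) combination at the
#' requested time point, exactly one signature column of the z-score matrix
#' and stacks them into a complete 3-dimensional tensor. Axis order follows
#' the supplied `cell_lines` / `compounds` lists so downstream output is
#' reproducible regardless of file order. Missing combinations and residual
#' ambiguity (e.g. several doses for one combination without a `dose_map`
#' filter) are hard errors, never silently averaged.
#'
#' @param mat Genes x signatures matrix from [read_zscore_matrix()].
#' @param metadata data.frame from [read_signature_metadata()].
#' @param time_point Time-point label to select (e.g. `"6 h"`).
#' @param cell_lines,compounds Character vectors fixing the tensor axes;
#'   default: all values observed at `time_point`, in first-appearance order.
#' @param dose_map Optional named character vector, compound -> dose label,
#'   applied before uniqueness is enforced.
#' @return A `ZScoreTensor`: list with `values` (G x R x C array, dimnames
#'   gene/cell line/compound), `time_point` and `dose_map`.
#' @export
assemble_tensor <- function(mat, metadata, time_point,
                            cell_lines = NULL, compounds = NULL,
                            dose_map = NULL) {
  meta <- metadata[metadata$time_point == time_point, , drop = FALSE]
  if (nrow(meta) == 0L)
    stop("no signatures at time point '", time_point, "'")
  if (is.null(cell_lines)) cell_lines <- unique(meta$cell_line)
  if (is.null(compounds)) compounds <- unique(meta$perturbagen)
  if (!is.null(dose_map)) {
    keep <- !(meta$perturbagen %in% names(dose_map)) |
      meta$dose == dose_map[meta$perturbagen]
    meta <- meta[keep, , drop = FALSE]
  }
  meta <- meta[meta$cell_line %in% cell_lines &
                 meta$perturbagen %in% compounds, , drop = FALSE]

  key <- paste(meta$cell_line, meta$perturbagen, sep = "\r")
  want <- expand.grid(cell_line = cell_lines, perturbagen = compounds,
                      stringsAsFactors = FALSE)
  want_key <- paste(want$cell_line, want$perturbagen, sep = "\r")
  counts <- table(key)
  missing_pairs <- want_key[!(want_key %in% key)]
  if (length(missing_pairs))
    stop("incomplete tensor: no signature for (cell line, compound) pair(s) ",
         paste(gsub("\r", " / ", missing_pairs), collapse = "; "),
         " at time point '", time_point, "'")
  ambiguous <- names(counts)[counts > 1L & names(counts) %in% want_key]
  if (length(ambiguous))
    stop("ambiguous tensor: multiple signatures for pair(s) ",
         paste(gsub("\r", " / ", ambiguous), collapse = "; "),
         "; disambiguate with `dose_map`")

  sig_for <- meta$signature_id[match(want_key, key)]
  absent <- setdiff(sig_for, colnames(mat))
  if (length(absent))
    stop("signature(s) referenced by metadata but absent from the matrix: ",
         paste(absent, collapse = ", "))

  G <- nrow(mat)
  values <- array(NA_real_, dim = c(G, length(cell_lines), length(compounds)),
                  dimnames = list(rownames(mat), cell_lines, compounds))
  for (k in seq_along(want_key)) {
    values[, want$cell_line[k], want$perturbagen[k]] <- mat[, sig_for[k]]
  }
  if (anyNA(values)) stop("assembled tensor contains missing values")
  structure(
    list(values = values, time_point = time_point, dose_map = dose_map),
    class = "ZScoreTensor"
  )
}

#' @export
print.ZScoreTensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ZScoreTensor: %d genes x %d cell lines x %d compounds at '%s'\n",
              d[1], d[2], d[3], x$time_point))
  invisible(x)
}

#' Dichotomize a z-score tensor into binary profiles
#'
#' A cell is significant iff `|Z| > threshold` (strict, so `|Z| = 2` is not
#' significant at the default threshold of 2). The test is sign-symmetric:
#' up- and down-regulation count alike.
#'
#' @param tensor A [assemble_tensor()] result.
#' @param threshold Absolute z-score cutoff (default 2.0).
#' @return Named list of [binary_profile()]s, one per gene, in tensor order.
#' @export
dichotomize <- function(tensor, threshold = 2.0) {
  stopifnot(inherits(tensor, "ZScoreTensor"), is.numeric(threshold))
  if (anyNA(tensor$values))
    stop("tensor contains missing values; profiles must be complete")
  genes <- dimnames(tensor$values)[[1]]
  profiles <- lapply(seq_along(genes), function(g) {
    slab <- tensor$values[g, , , drop = TRUE]
    if (is.null(dim(slab)))
      slab <- matrix(slab, dim(tensor$values)[2], dim(tensor$values)[3],
                     dimnames = dimnames(tensor$values)[2:3])
    binary_profile((abs(slab) > threshold) * 1L, gene_id = genes[g])
  })
  names(profiles) <- genes
  profiles
}
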