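#' Build the gene / cell-line / compound association network
#'
#' Every significant gene contributes one edge per member of its optimal
#' pattern: gene -- cell line for each selected row, gene -- compound for
#' each selected column. Non-significant genes contribute nothing, so the
#' network has no orphan factor nodes.
#'
#' @param records Output of [run_significance()].
#' @return An [igraph][igraph::igraph-package] graph whose vertices carry a
#'   `type` attribute in `{"gene", "cell_line", "compound"}` and whose edges
#'   carry `factor_type`.
#' @export
build_network <- function(records) {
  stopifnot(is.data.frame(records))
  sig <- records[records$significant, , drop = FALSE]
  split_labels <- function(x) if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]] else character(0)
  edges <- do.call(rbind, lapply(seq_len(nrow(sig)), function(k) {
    rows <- split_labels(sig$pattern_rows[k])
    cols <- split_labels(sig$pattern_cols[k])
    data.frame(
      gene = rep(sig$gene_id[k], length(rows) + length(cols)),
      factor = c(rows, cols),
      factor_type = c(rep("cell_line", length(rows)),
                      rep("compound", length(cols))),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  vertices <- rbind(
    data.frame(name = unique(edges$gene), type = "gene",
               stringsAsFactors = FALSE),
    unique(data.frame(name = edges$factor, type = edges$factor_type,
                      stringsAsFactors = FALSE))
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export / import an association network
#'
#' `"tsv"` writes the edge list with columns `gene`, `factor`, `factor_type`
#' (header-only for an empty network); `"graphml"` writes GraphML with the
#' vertex `type` attribute preserved. Re-import reproduces the network
#' exactly up to vertex order.
#'
#' @param net Graph from [build_network()].
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path` invisibly; `read_network()` returns the graph.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  if (igraph::ecount(net) == 0L) {
    writeLines("gene\tfactor\tfactor_type", path)
    return(invisible(path))
  }
  ends <- igraph::as_edgelist(net)
  types <- igraph::V(net)$type
  names(types) <- igraph::V(net)$name
  # orient each edge gene -> factor regardless of storage order
  gene_first <- types[ends[, 1]] == "gene"
  df <- data.frame(
    gene = ifelse(gene_first, ends[, 1], ends[, 2]),
    factor = ifelse(gene_first, ends[, 2], ends[, 1]),
    factor_type = igraph::E(net)$factor_type,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  vertices <- rbind(
    data.frame(name = unique(df$gene), type = "gene",
               stringsAsFactors = FALSE),
    unique(data.frame(name = df$factor, type = df$factor_type,
                      stringsAsFactors = FALSE))
  )
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = vertices)
}
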