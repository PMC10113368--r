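#' End-to-end run configuration
#'
#' Bundles every knob of the pipeline. Defaults match the method's stated
#' operating point: dichotomization at |Z| > 2, L = 10,000 permutations per
#' group, significance at the 5% FDR level.
#'
#' @param matrix_path Path to the z-score matrix file.
#' @param metadata_path Path to the signature metadata table.
#' @param format Matrix dialect for [read_zscore_matrix()].
#' @param time_point Time-point label to assemble.
#' @param cell_lines,compounds Optional axis selections (default: all
#'   observed at `time_point`).
#' @param dose_map Optional compound -> dose filter.
#' @param threshold Dichotomization cutoff (default 2.0).
#' @param ga GA settings, a [ga_config()].
#' @param L Permutations per null distribution (default 10,000).
#' @param alpha FDR level (default 0.05).
#' @param pseudocount Use add-one smoothing for p-values.
#' @param tie_policy Optimizer tie policy.
#' @param optimizer `"auto"`, `"exhaustive"` or `"ga"`.
#' @param seed Base seed; per-gene and per-group seeds derive from it.
#' @param out_dir Output directory for the result bundle.
#' @return A `RunConfig` object.
#' @export
run_config <- function(matrix_path, metadata_path, format = "auto",
                       time_point = "6 h", cell_lines = NULL,
                       compounds = NULL, dose_map = NULL, threshold = 2.0,
                       ga = ga_config(), L = 10000L, alpha = 0.05,
                       pseudocount = FALSE,
                       tie_policy = c("seeded_random", "deterministic"),
                       optimizer = c("auto", "exhaustive", "ga"),
                       seed = 1L, out_dir = "factorpat_out") {
  structure(
    list(matrix_path = matrix_path, metadata_path = metadata_path,
         format = format, time_point = time_point, cell_lines = cell_lines,
         compounds = compounds, dose_map = dose_map, threshold = threshold,
         ga = ga, L = as.integer(L), alpha = alpha,
         pseudocount = isTRUE(pseudocount),
         tie_policy = match.arg(tie_policy),
         optimizer = match.arg(optimizer),
         seed = as.integer(seed), out_dir = out_dir),
    class = "RunConfig"
  )
}

#' Run the full pattern-mining pipeline
#'
#' Stages, in order: read matrix + metadata, assemble the complete tensor at
#' the requested time point, dichotomize, fit each gene's optimal
#' factor-specific pattern, build one permutation null per observed group
#' size, compute p- and q-values, flag significant genes, build and export
#' the association network. Identical config + seed reproduce identical
#' outputs. A JSON manifest records the config, per-stage counts, genes per
#' group, and session versions.
#'
#' @param config A [run_config()].
#' @param null_cache Optional prebuilt null cache (see [build_null_cache()]).
#' @return Invisibly, a list with `records`, `network`, `nulls`, `manifest`
#'   and the written `paths`.
#' @export
run_pipeline <- function(config, null_cache = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()
  stage <- function(what, expr) {
    tic <- Sys.time()
    value <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
    list(value = value, seconds = as.numeric(Sys.time() - tic, units = "secs"))
  }

  rd <- stage("read", {
    mat <- read_zscore_matrix(config$matrix_path, config$format)
    meta <- read_signature_metadata(config$metadata_path)
    list(mat = mat, meta = meta)
  })
  asm <- stage("assemble", assemble_tensor(
    rd$value$mat, rd$value$meta, config$time_point,
    config$cell_lines, config$compounds, config$dose_map))
  dich <- stage("dichotomize", dichotomize(asm$value, config$threshold))
  sig <- stage("significance", run_significance(
    dich$value, alpha = config$alpha, L = config$L,
    optimizer = config$optimizer, ga_config = config$ga,
    tie_policy = config$tie_policy, pseudocount = config$pseudocount,
    seed = config$seed, null_cache = null_cache))
  records <- sig$value
  net <- stage("network", build_network(records))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    records = file.path(config$out_dir, "records.tsv"),
    edges = file.path(config$out_dir, "network_edges.tsv"),
    graphml = file.path(config$out_dir, "network.graphml"),
    null_cache = file.path(config$out_dir, "null_cache.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write.table(records, paths$records, sep = "\t", quote = FALSE,
              row.names = FALSE)
  export_network(net$value, paths$edges, "tsv")
  export_network(net$value, paths$graphml, "graphml")
  write_null_cache(attr(records, "nulls"), paths$null_cache)

  genes_per_group <- table(records$n)
  manifest <- list(
    config = config[setdiff(names(config), "ga")],
    ga = unclass(config$ga),
    counts = list(
      genes = nrow(records),
      cell_lines = attr(records, "grid_dim")[1],
      compounds = attr(records, "grid_dim")[2],
      significant = sum(records$significant),
      effect_classes = as.list(table(records$effect_class[records$significant])),
      genes_per_group = as.list(genes_per_group)
    ),
    timings_seconds = list(read = rd$seconds, assemble = asm$seconds,
                           dichotomize = dich$seconds,
                           significance = sig$seconds,
                           network = net$seconds),
    versions = list(factorpat = as.character(utils::packageVersion("factorpat")),
                    R = as.character(getRversion())),
    total_seconds = as.numeric(Sys.time() - t0, units = "secs")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(records = records, network = net$value,
                 nulls = attr(records, "nulls"), manifest = manifest,
                 paths = paths))
}
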