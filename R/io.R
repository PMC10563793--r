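#' Read and write the pipeline's tab-delimited tables
#'
#' All tables move as plain TSV with a header row: the gene table
#' (`gene_id chromosome order_index intron_count segment_id`), paralog pairs
#' (`gene_a gene_b duplication_node`), ohnolog sets (`gene_a gene_b`),
#' consensus labels, feature tables, and the expression matrix (genes x
#' conditions with gene ids in the first column). Simulation configs
#' round-trip as YAML.
#'
#' @param path file path.
#' @param x object to write.
#' @name io
NULL

#' @rdname io
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' @rdname io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write_tsv_table(df, path)
}

#' Write all tables of a simulated genome to a directory
#'
#' Writes `genes.tsv`, `pairs.tsv`, `segments.tsv`, `truth.tsv` (with a
#' `true_class` column) and `config.yaml` under `dir`.
#'
#' @param sim output of [simulate_genome].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(sim$genes, file.path(dir, "genes.tsv"))
  write_tsv_table(sim$pairs, file.path(dir, "pairs.tsv"))
  write_tsv_table(sim$segments, file.path(dir, "segments.tsv"))
  write_tsv_table(sim$truth$gene_truth, file.path(dir, "truth.tsv"))
  write_simulation_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname io
#' @export
write_simulation_config <- function(x, path) {
  stopifnot(inherits(x, "simulation_config"))
  out <- unclass(x)
  # named atomic vectors must become maps or yaml drops the names
  for (nm in c("node_age_table", "expr_breadth", "expr_level_log"))
    out[[nm]] <- as.list(out[[nm]])
  out$feature_specs <- lapply(out$feature_specs, function(sp) {
    sp$shift <- as.list(sp$shift)
    sp
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname io
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$node_age_table <- unlist(raw$node_age_table)
  raw$expr_breadth <- unlist(raw$expr_breadth)
  raw$expr_level_log <- unlist(raw$expr_level_log)
  raw$feature_specs <- lapply(raw$feature_specs, function(sp) {
    sp$shift <- unlist(sp$shift)
    sp
  })
  do.call(simulation_config, raw)
}
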