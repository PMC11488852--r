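#' Read and write pipeline file formats
#'
#' Plain-text contracts for the pipeline stages: counts as TSV with genes in
#' rows and samples in columns (first column `gene`), sample metadata as
#' CSV, differential-expression results as TSV with columns
#' `(gene, log2fc, t, p, p_adj)`, allele depth tables as TSV, mating trials
#' as CSV, and network edge lists as TSV `(gene_i, gene_j, a_ij)` filtered
#' at an export threshold.
#'
#' @param counts,path,metadata,de,depths,trials Objects/paths as named.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline_io
#' @export
write_metadata_csv <- function(metadata, path) {
  readr::write_csv(tibble::as_tibble(metadata), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_metadata_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_de_tsv <- function(de, path) {
  readr::write_tsv(de_table(de), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_de_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_allele_depths_tsv <- function(depths, path) {
  readr::write_tsv(tibble::as_tibble(depths), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_allele_depths_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(tibble::as_tibble(trials), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Export a weighted edge list
#'
#' @param adj Adjacency matrix.
#' @param threshold Minimum adjacency to export.
#' @return Tibble with columns `gene_i`, `gene_j`, `a_ij` (upper triangle
#'   only).
#' @export
edge_list <- function(adj, threshold = 0.1) {
  idx <- which(upper.tri(adj) & adj >= threshold, arr.ind = TRUE)
  tibble::tibble(
    gene_i = rownames(adj)[idx[, 1]],
    gene_j = colnames(adj)[idx[, 2]],
    a_ij = adj[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$a_ij), .data$gene_i, .data$gene_j)
}
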