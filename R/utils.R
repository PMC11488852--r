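# internal validation helpers

assert_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric matrix (genes in rows, samples in columns).", arg))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate gene IDs in count matrix.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample IDs in count matrix.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  invisible(counts)
}

assert_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", arg))
  }
  invisible(x)
}

# deterministic gene identifiers: gene_0001, gene_0002, ...
gene_ids <- function(n, prefix = "gene") {
  sprintf("%s_%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}
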