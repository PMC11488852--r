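#' Connection scores against a seed gene family
#'
#' For every non-seed transcript i, computes
#' `C_i = sum_j a_ij * |F_j|` over the seed genes j (here the Obp56h
#' family), where `a_ij` is the soft-thresholded network adjacency and
#' `F_j` the seed gene's log2 fold-change between male types. Weighting by
#' `|F_j|` prioritizes connections to seed genes that are more
#' differentially expressed. Seed genes are excluded from their own ranking;
#' self-adjacency is never used.
#'
#' @param adj Adjacency matrix.
#' @param seed_genes Character vector of seed gene IDs (non-empty, present
#'   in both `adj` and `fold_changes`).
#' @param fold_changes A `protoy_de` object or a data frame with columns
#'   `gene` and `log2fc`.
#'
#' @return Tibble with columns `gene`, `score`, `rank` (descending score,
#'   ties broken by ascending gene ID).
#' @export
connection_scores <- function(adj, seed_genes, fold_changes) {
  if (!length(seed_genes)) abort("Seed gene set is empty.")
  fc <- de_table(fold_changes)
  missing_adj <- setdiff(seed_genes, rownames(adj))
  if (length(missing_adj)) {
    abort(paste0("Seed gene(s) absent from adjacency: ", paste(missing_adj, collapse = ", ")))
  }
  missing_fc <- setdiff(seed_genes, fc$gene)
  if (length(missing_fc)) {
    abort(paste0("Seed gene(s) without a fold-change: ", paste(missing_fc, collapse = ", ")))
  }
  absF <- abs(setNames(fc$log2fc, fc$gene)[seed_genes])
  others <- setdiff(rownames(adj), seed_genes)
  scores <- as.numeric(adj[others, seed_genes, drop = FALSE] %*% absF)
  ord <- order(-scores, others)
  tibble::tibble(gene = others, score = scores)[ord, ] |>
    dplyr::mutate(rank = dplyr::row_number())
}

de_table <- function(fold_changes) {
  if (inherits(fold_changes, "protoy_de")) {
    return(fold_changes$table)
  }
  tab <- tibble::as_tibble(fold_changes)
  stopifnot(all(c("gene", "log2fc") %in% names(tab)))
  tab
}

#' Central genes: the top of the connection-score ranking
#'
#' Either the `k` highest-scoring genes (default `k = 100`, the "central
#' gene" classification) or the top `round(top_fraction * n)` genes
#' (rounded to the nearest count, minimum 1, so that 0.55% of 18,182
#' scored transcripts corresponds to the same 100 genes). Ties are resolved
#' by ascending gene ID, so the selected set is deterministic.
#'
#' @param scores Tibble from [connection_scores()].
#' @param k Number of genes; mutually exclusive with `top_fraction`.
#' @param top_fraction Fraction in `(0, 1]`.
#' @return Character vector of gene IDs.
#' @export
central_genes <- function(scores, k = NULL, top_fraction = NULL) {
  if (!is.null(k) && !is.null(top_fraction)) {
    abort("Give either `k` or `top_fraction`, not both.")
  }
  n <- nrow(scores)
  if (is.null(k)) {
    if (is.null(top_fraction)) k <- 100L
    else {
      if (top_fraction <= 0 || top_fraction > 1) abort("`top_fraction` must lie in (0, 1].")
      k <- max(1L, round(top_fraction * n))
    }
  }
  if (k > n) abort("`k` exceeds the number of scored genes.")
  scores$gene[order(scores$rank)][seq_len(k)]
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the conventional rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose probability
#' is at most that of the observed table. The reported odds ratio is the
#' sample odds ratio `(a d) / (b c)` (0 and Inf conventions for zero
#' cells), not a conditional maximum-likelihood estimate.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A list of class `protoy_fisher`: `table`, `odds_ratio`,
#'   `p`, and `degenerate` (`TRUE` when a margin is zero, in which case
#'   `p = 1` and the odds ratio is undefined).
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must be a 2x2 matrix of non-negative integers.")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(c(a + b, c_ + d, a + c_, b + d) == 0)) {
    return(structure(
      list(table = tab, odds_ratio = NA_real_, p = 1, degenerate = TRUE),
      class = "protoy_fisher"
    ))
  }
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  m <- a + b # row 1 margin
  n2 <- c_ + d
  k <- a + c_ # column 1 margin
  support <- max(0, k - n2):min(k, m)
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  structure(
    list(table = tab, odds_ratio = or, p = min(p, 1), degenerate = FALSE),
    class = "protoy_fisher"
  )
}

#' @export
print.protoy_fisher <- function(x, ...) {
  cat("Fisher's exact test\n")
  print(x$table)
  if (x$degenerate) {
    cat("Degenerate margin: p = 1, odds ratio undefined\n")
  } else {
    cat(sprintf("Sample odds ratio = %.4g, two-sided p = %.4g\n", x$odds_ratio, x$p))
  }
  invisible(x)
}

#' Chromosome enrichment of a gene set
#'
#' Builds the 2x2 table (in-set vs out-of-set) x (focal chromosome vs all
#' other chromosomes) and delegates to [fisher_exact()]. Genes without a
#' chromosome assignment (`NA`) are excluded from the universe, matching
#' the counting convention used for house fly scaffold-level annotation.
#'
#' @param geneset Character vector of gene IDs (e.g. the central genes).
#' @param annotation Data frame with columns `gene` and `chromosome`
#'   (`NA` = unplaced).
#' @param focal Focal chromosome label (e.g. `"III"`).
#' @return A `protoy_fisher` object with an extra element `counts`
#'   recording the table used.
#' @export
chromosome_enrichment <- function(geneset, annotation, focal) {
  ann <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene", "chromosome") %in% names(ann)))
  ann <- dplyr::filter(ann, !is.na(.data$chromosome))
  if (!focal %in% ann$chromosome) {
    abort(sprintf("Focal chromosome '%s' absent from the annotation.", focal))
  }
  in_set <- ann$gene %in% geneset
  on_focal <- ann$chromosome == focal
  tab <- matrix(
    c(
      sum(in_set & on_focal), sum(in_set & !on_focal),
      sum(!in_set & on_focal), sum(!in_set & !on_focal)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("in_set", "out_set"), c("focal", "other"))
  )
  out <- fisher_exact(tab)
  out$counts <- tab
  out
}

#' Direction enrichment of a gene family
#'
#' Tests whether a gene family (e.g. the nine Obp56h genes) contains an
#' excess of genes with higher expression in Y^M males, regardless of
#' significance. With the III^M - Y^M fold-change orientation, "higher in
#' Y^M" means `log2fc < 0`; genes with a fold-change of exactly 0 count as
#' not higher in Y^M (conservative). The 2x2 table
#' (family vs other genes) x (higher in Y^M or not) goes to
#' [fisher_exact()].
#'
#' @param fold_changes A `protoy_de` object or data frame with `gene`,
#'   `log2fc`.
#' @param family Character vector of family gene IDs (non-empty subset of
#'   the fold-change genes).
#' @return A `protoy_fisher` object with element `counts`.
#' @export
sign_enrichment <- function(fold_changes, family) {
  if (!length(family)) abort("Family gene set is empty.")
  fc <- de_table(fold_changes)
  missing <- setdiff(family, fc$gene)
  if (length(missing)) {
    abort(paste0("Family gene(s) without a fold-change: ", paste(missing, collapse = ", ")))
  }
  in_family <- fc$gene %in% family
  higher_ym <- fc$log2fc < 0
  tab <- matrix(
    c(
      sum(in_family & higher_ym), sum(in_family & !higher_ym),
      sum(!in_family & higher_ym), sum(!in_family & !higher_ym)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("family", "other"), c("higher_in_YM", "not_higher"))
  )
  out <- fisher_exact(tab)
  out$counts <- tab
  out
}
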