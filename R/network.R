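#' Pearson correlation matrix across samples
#'
#' @param expr Expression matrix, genes x samples. Genes with zero variance
#'   across samples are dropped with a warning.
#' @return Symmetric correlation matrix (genes x genes), unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3) abort("Need at least 3 samples for co-expression analysis.")
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    warn(sprintf("Dropping %d zero-variance gene(s).", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- cor(t(expr))
  diag(r) <- 1
  r
}

#' Soft-threshold (unsigned) adjacency
#'
#' `a_ij = |r_ij|^beta` with unit diagonal. The absolute value makes the
#' network unsigned: strongly positively and strongly negatively correlated
#' gene pairs are both strongly connected.
#'
#' @param corr Correlation matrix.
#' @param beta Positive integer soft-threshold power.
#' @return Adjacency matrix in `[0, 1]` with attribute `beta`.
#' @export
adjacency <- function(corr, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1 || beta != round(beta)) {
    abort("`beta` must be an integer >= 1.")
  }
  a <- abs(corr)^beta
  diag(a) <- 1
  attr(a, "beta") <- as.integer(beta)
  a
}

#' Choose the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power, the connectivity `k_i = sum_{j != i} a_ij` is
#' computed, binned into `n_bins` equal-width bins, and `log10` frequency
#' is regressed on `log10` mean connectivity per bin (the conventional
#' scale-free fit index). The
#' chosen power is the smallest candidate whose fit R-squared reaches
#' `rsq_cut` while mean connectivity stays at or above `mean_k_min` (the
#' latter interpreted as a minimum acceptable mean connectivity; see the
#' methods vignette for why this reading of the threshold is a recorded
#' convention). If no candidate satisfies both, the power with the largest
#' R-squared is returned with `warning_flag = TRUE`.
#'
#' @param corr Correlation matrix.
#' @param candidate_betas Integer vector of candidate powers (the default
#'   includes 7, the power selected for the house fly head network).
#' @param rsq_cut Scale-free fit R-squared threshold.
#' @param mean_k_min Minimum acceptable mean connectivity.
#' @param n_bins Number of equal-count connectivity bins.
#'
#' @return A list of class `protoy_sft`: `beta` (chosen power), `fit`
#'   (tibble with per-candidate `beta`, `rsq`, `slope`, `mean_k`),
#'   `warning_flag`, and `reference_beta = 7L` for comparison.
#' @export
pick_soft_threshold <- function(corr, candidate_betas = 1:12, rsq_cut = 0.8,
                                mean_k_min = 0.7, n_bins = 10) {
  if (!length(candidate_betas)) abort("`candidate_betas` must be non-empty.")
  fit <- purrr::map_dfr(sort(unique(as.integer(candidate_betas))), function(b) {
    a <- adjacency(corr, b)
    k <- colSums(a) - 1
    sf <- scale_free_fit(k, n_bins)
    tibble::tibble(beta = b, rsq = sf$rsq, slope = sf$slope, mean_k = mean(k))
  })
  ok <- fit$rsq >= rsq_cut & fit$mean_k >= mean_k_min
  if (any(ok)) {
    beta <- fit$beta[which(ok)[1]]
    flag <- FALSE
  } else {
    beta <- fit$beta[which.max(fit$rsq)]
    flag <- TRUE
    warn("No candidate power met both the scale-free fit and mean-connectivity thresholds; returning the best-fitting power.")
  }
  structure(
    list(beta = beta, fit = fit, warning_flag = flag, reference_beta = 7L),
    class = "protoy_sft"
  )
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) {
    return(list(rsq = NA_real_, slope = NA_real_))
  }
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  x <- log10(mk[keep])
  y <- log10(freq[keep])
  if (length(x) < 3 || var(x) == 0) {
    return(list(rsq = NA_real_, slope = NA_real_))
  }
  f <- lm.fit(cbind(1, x), y)
  rsq <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  list(rsq = rsq, slope = unname(f$coefficients[2]))
}

#' @export
print.protoy_sft <- function(x, ...) {
  cat(
    "Soft-threshold selection: beta =", x$beta,
    if (x$warning_flag) "(best fit; thresholds not met)" else "",
    "| reference beta =", x$reference_beta, "\n"
  )
  print(x$fit, n = nrow(x$fit))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1. Topological overlap credits two genes both for their
#' direct adjacency and for sharing network neighbors.
#'
#' @param adj Adjacency matrix with values in `[0, 1]`.
#' @return Symmetric TOM matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adj) {
  if (any(adj < 0 | adj > 1)) abort("Adjacency values must lie in [0, 1].")
  a <- adj
  diag(a) <- 0
  l <- a %*% a # l_ij = sum_u a_iu a_uj, u != i,j since diag = 0
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  w[kmin + 1 - a == 0] <- 0
  diag(w) <- 1
  dimnames(w) <- dimnames(adj)
  w
}

#' Detect co-expression modules from topological overlap
#'
#' Genes are clustered by average-linkage hierarchical clustering on the
#' dissimilarity `1 - TOM`. The tree is cut statically at the candidate
#' height that maximizes weighted modularity of the induced partition on the
#' TOM similarity graph; clusters smaller than `min_size` are relabeled
#' unassigned (module 0); finally, modules whose eigengenes have
#' dissimilarity `1 - cor` below `merge_threshold` are merged iteratively
#' (closest pair first) until stable. The procedure is deterministic.
#'
#' @param tom TOM matrix.
#' @param expr Expression matrix (genes x samples) used for eigengene
#'   merging; must contain every gene in `tom`.
#' @param min_size Minimum module size.
#' @param merge_threshold Eigengene dissimilarity below which modules merge.
#' @param n_heights Number of candidate cut heights scanned.
#'
#' @return A tibble with columns `gene` and `module` (`"0"` = unassigned;
#'   modules labeled `"1"`, `"2"`, ... in decreasing size order).
#' @export
detect_modules <- function(tom, expr, min_size = 30, merge_threshold = 0.2,
                           n_heights = 50) {
  genes <- rownames(tom)
  n <- nrow(tom)
  if (min_size > n) {
    warn("`min_size` exceeds the number of genes; all genes unassigned.")
    return(tibble::tibble(gene = genes, module = "0"))
  }
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")

  heights <- quantile(hc$height, probs = seq(0.02, 0.98, length.out = n_heights))
  heights <- unique(heights)
  w <- tom
  diag(w) <- 0
  total_w <- sum(w)
  best <- NULL
  best_q <- -Inf
  for (h in heights) {
    cl <- cutree(hc, h = h)
    if (max(cl) < 2 || max(cl) >= n) next
    q <- weighted_modularity(w, cl, total_w)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- cl
    }
  }
  if (is.null(best)) best <- rep(1L, n)

  # size filter
  sizes <- table(best)
  small <- as.integer(names(sizes)[sizes < min_size])
  cl <- ifelse(best %in% small, 0L, best)
  if (all(cl == 0L)) {
    return(tibble::tibble(gene = genes, module = "0"))
  }

  # eigengene merging
  repeat {
    labs <- sort(unique(cl[cl != 0L]))
    if (length(labs) < 2) break
    me <- sapply(labs, function(m) {
      eigengene_vector(expr[genes[cl == m], , drop = FALSE])
    })
    d <- 1 - cor(me)
    diag(d) <- Inf
    if (min(d) >= merge_threshold) break
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    keep <- labs[min(idx)]
    drop <- labs[max(idx)]
    cl[cl == drop] <- keep
  }

  # relabel by decreasing size
  labs <- sort(unique(cl[cl != 0L]))
  sizes <- vapply(labs, function(m) sum(cl == m), integer(1))
  new <- setNames(as.character(seq_along(labs)), labs[order(-sizes, labs)])
  module <- ifelse(cl == 0L, "0", new[as.character(cl)])
  tibble::tibble(gene = genes, module = unname(module))
}

weighted_modularity <- function(w, cl, total_w = sum(w)) {
  if (total_w == 0) {
    return(0)
  }
  strength <- rowSums(w)
  q <- 0
  for (m in unique(cl)) {
    idx <- cl == m
    q <- q + sum(w[idx, idx]) / total_w - (sum(strength[idx]) / total_w)^2
  }
  q
}

# first right singular vector of the gene-standardized submatrix,
# sign-aligned with the mean standardized profile
eigengene_vector <- function(sub) {
  z <- t(scale(t(sub)))
  if (any(!is.finite(z))) abort("Module contains zero-variance genes; eigengene undefined.")
  v <- svd(z, nu = 0, nv = 1)$v[, 1]
  m <- colMeans(z)
  if (sd(m) > 0 && cor(v, m) < 0) v <- -v
  v
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of its
#' gene-standardized expression submatrix: a unit-norm per-sample summary
#' profile, sign-aligned so its correlation with the module's mean
#' standardized expression is non-negative.
#'
#' @param expr Expression matrix, genes x samples.
#' @param modules Tibble from [detect_modules()] (columns `gene`,
#'   `module`); unassigned genes (module `"0"`) are ignored.
#'
#' @return A samples x modules numeric matrix, columns named `ME<module>`.
#' @export
module_eigengenes <- function(expr, modules) {
  labs <- sort(unique(modules$module[modules$module != "0"]))
  if (!length(labs)) abort("No assigned modules.")
  me <- sapply(labs, function(m) {
    genes <- modules$gene[modules$module == m]
    eigengene_vector(expr[genes, , drop = FALSE])
  })
  colnames(me) <- paste0("ME", labs)
  rownames(me) <- colnames(expr)
  me
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with a sample trait (e.g.
#' genotype coded 0/1), with two-sided t-distribution p-values and
#' Benjamini-Hochberg adjustment across modules.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param trait Numeric vector of length `nrow(eigengenes)`.
#' @return Tibble with columns `module`, `r`, `p`, `p_adj`.
#' @export
module_trait_association <- function(eigengenes, trait) {
  n <- nrow(eigengenes)
  if (n < 3) abort("Need at least 3 samples.")
  if (var(trait) == 0) abort("Trait is constant.")
  r <- as.numeric(cor(eigengenes, trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    module = sub("^ME", "", colnames(eigengenes)),
    r = r, p = p, p_adj = adjust_fdr(p)
  )
}

#' Intramodular connectivity (kWithin)
#'
#' `kWithin_i` is the sum of gene i's adjacencies to the other genes in its
#' module; unassigned genes get 0. High kWithin defines module hub genes.
#'
#' @param adj Adjacency matrix.
#' @param modules Tibble with columns `gene`, `module`.
#' @return Tibble with columns `gene`, `module`, `k_within`, sorted as the
#'   adjacency rows.
#' @export
intramodular_connectivity <- function(adj, modules) {
  genes <- rownames(adj)
  mod <- setNames(modules$module, modules$gene)[genes]
  kw <- numeric(length(genes))
  for (m in unique(mod[mod != "0"])) {
    idx <- which(mod == m)
    sub <- adj[idx, idx, drop = FALSE]
    diag(sub) <- 0
    kw[idx] <- rowSums(sub)
  }
  tibble::tibble(gene = genes, module = unname(mod), k_within = kw)
}
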