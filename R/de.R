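#' Filter genes by counts-per-million
#'
#' Keeps genes with at least `cpm_threshold` counts per million in at least
#' `min_samples` samples; the defaults (0.5 CPM in >= 4 samples) are the
#' standard low-expression filter for this study design.
#'
#' @param counts Numeric matrix, genes x samples, with dimnames.
#' @param cpm_threshold Minimum counts-per-million.
#' @param min_samples Minimum number of samples meeting the threshold.
#'
#' @return The filtered count matrix, gene order preserved. Warns (does not
#'   error) if no gene survives.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 0.5, min_samples = 4) {
  assert_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("All library sizes (column sums) must be positive.")
  cpm <- t(t(counts) / lib) * 1e6
  keep <- rowSums(cpm >= cpm_threshold) >= min_samples
  if (!any(keep)) warn("No gene passed the expression filter; returning an empty matrix.")
  counts[keep, , drop = FALSE]
}

#' Variance-stabilizing normalization of counts
#'
#' Computes median-of-ratios size factors against the geometric-mean
#' reference sample (over genes with all-positive counts) and returns
#' `log2(count / size_factor + 1)`. This is a parameter-free
#' variance-stabilizing transform: it removes depth differences and flattens
#' the count-variance/mean relationship, which is the property the
#' downstream linear modeling and network construction rely on.
#'
#' @param counts Numeric matrix, genes x samples.
#'
#' @return Numeric matrix of the same shape with attribute `size_factors`.
#'   Falls back to library-size factors (scaled to geometric mean 1), with a
#'   warning, when no gene has all-positive counts.
#' @export
normalize_vst <- function(counts) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) abort("Need at least 2 samples.")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(x) {
      exp(median(log(x) - logref))
    })
  } else {
    warn("No gene with all-positive counts; using library-size size factors.")
    lib <- colSums(counts)
    sf <- lib / exp(mean(log(lib)))
  }
  expr <- log2(t(t(counts) / sf) + 1)
  attr(expr, "size_factors") <- sf
  expr
}

#' Estimate surrogate variables from expression residuals
#'
#' Captures latent sources of sample-level variation (batch and other
#' unmodeled structure) as orthonormal vectors in the residual space of the
#' primary design: the genotype model is fit per gene, the residual matrix
#' is decomposed by SVD, and the number of components `k` is chosen by
#' permutation-based parallel analysis (each gene's residuals are permuted
#' independently across samples, and a component is kept while its singular
#' value exceeds the `1 - alpha` quantile of its permuted counterparts).
#'
#' @param expr Expression matrix, genes x samples (variance-stabilized).
#' @param design Either a factor/vector of length `ncol(expr)` (the primary
#'   variable, e.g. genotype) or a design matrix with an intercept.
#' @param n_sv Number of surrogate variables, or `"auto"` for parallel
#'   analysis.
#' @param n_perm Number of permutations used by parallel analysis.
#' @param alpha Per-component significance level for parallel analysis.
#'
#' @return A samples x k numeric matrix (columns `SV1`, ...), possibly with
#'   zero columns. Every column is orthogonal to the design columns.
#' @export
estimate_surrogate_variables <- function(expr, design, n_sv = "auto",
                                         n_perm = 20, alpha = 0.05) {
  X <- design_matrix(design, ncol(expr))
  n <- ncol(expr)
  rdf <- n - ncol(X)
  if (rdf <= 0) abort("More design columns than samples.")
  if (is.numeric(n_sv) && n_sv >= rdf) {
    abort(sprintf("`n_sv` must be below the residual degrees of freedom (%d).", rdf))
  }
  res <- residual_matrix(expr, X)
  sv_all <- svd(res)
  max_k <- min(rdf - 1L, sum(sv_all$d > 1e-10))

  if (identical(n_sv, "auto")) {
    d_obs <- sv_all$d
    d_null <- matrix(0, n_perm, length(d_obs))
    for (b in seq_len(n_perm)) {
      # permute each gene's expression across samples and rerun the
      # residualization: the null spectrum then has the same per-row norms
      # and the same rank constraint as the observed residual spectrum
      perm <- residual_matrix(t(apply(expr, 1, sample)), X)
      d_null[b, ] <- svd(perm, nu = 0, nv = 0)$d
    }
    thresh <- apply(d_null, 2, quantile, probs = 1 - alpha)
    k <- 0L
    for (j in seq_len(max_k)) {
      if (d_obs[j] > thresh[j]) k <- j else break
    }
  } else {
    k <- min(as.integer(n_sv), max_k)
  }
  sv <- sv_all$v[, seq_len(k), drop = FALSE]
  colnames(sv) <- if (k > 0) paste0("SV", seq_len(k)) else character()
  rownames(sv) <- colnames(expr)
  sv
}

design_matrix <- function(design, n_samples) {
  if (is.matrix(design)) {
    X <- design
  } else {
    if (length(design) != n_samples) {
      abort("`design` length must equal the number of samples.")
    }
    X <- model.matrix(~ factor(design))
  }
  if (qr(X)$rank < ncol(X)) abort("Design matrix is rank deficient.")
  X
}

residual_matrix <- function(expr, X) {
  H <- X %*% solve(crossprod(X), t(X))
  expr - expr %*% t(H) # (I - H) applied in sample space
}

#' Moderated differential-expression fit
#'
#' Fits, per gene, an ordinary least-squares model of expression on genotype
#' plus optional surrogate variables, then shrinks residual variances toward
#' a common prior by empirical-Bayes moment matching on the log residual
#' variances (a scaled inverse-chi-square prior whose degrees of freedom and
#' scale are estimated from the digamma/trigamma moments of `log s^2`). The
#' genotype contrast is reported as a moderated t statistic with
#' `df + prior df` degrees of freedom.
#'
#' The fold-change orientation is III^M minus Y^M: positive `log2fc` means
#' higher expression in III^M males.
#'
#' @param expr Expression matrix, genes x samples (variance-stabilized,
#'   log2 scale).
#' @param genotype Factor/character of length `ncol(expr)` with levels
#'   `YM` and `IIIM` (other labels: the second sorted level is the
#'   numerator).
#' @param sv Optional samples x k surrogate-variable matrix from
#'   [estimate_surrogate_variables()].
#' @param shrink If `FALSE`, no empirical-Bayes shrinkage is applied and the
#'   statistics are the classical regression t.
#'
#' @return An object of class `protoy_de`; `tidy()` returns a tibble with
#'   columns `gene`, `log2fc`, `t`, `p`, `p_adj`.
#' @export
fit_de_model <- function(expr, genotype, sv = NULL, shrink = TRUE) {
  if (length(genotype) != ncol(expr)) {
    abort("`genotype` length must equal the number of samples.")
  }
  g <- factor(genotype)
  if (nlevels(g) != 2) abort("`genotype` must have exactly two levels.")
  if (all(c("YM", "IIIM") %in% levels(g))) g <- factor(g, levels = c("YM", "IIIM"))
  X <- model.matrix(~g)
  colnames(X) <- c("(Intercept)", "genotype")
  if (!is.null(sv) && ncol(sv) > 0) X <- cbind(X, sv)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    abort(paste0("Rank-deficient design; collinear columns: ", paste(bad, collapse = ", ")))
  }

  fit <- lm.fit(X, t(expr))
  coefs <- t(fit$coefficients)
  res <- t(fit$residuals)
  df <- ncol(expr) - ncol(X)
  if (df <= 0) abort("No residual degrees of freedom.")
  s2 <- rowSums(res^2) / df
  xtxi <- solve(crossprod(X))
  unscaled_se <- sqrt(xtxi["genotype", "genotype"])
  beta <- coefs[, "genotype"]

  if (shrink) {
    prior <- fit_variance_prior(s2, df)
    if (is.infinite(prior$df0)) {
      # variances no more dispersed than chi-square sampling: full shrinkage
      s2_post <- rep(prior$s02, length(s2))
      df_total <- Inf
    } else {
      s2_post <- (prior$df0 * prior$s02 + df * s2) / (prior$df0 + df)
      df_total <- df + prior$df0
    }
  } else {
    prior <- list(df0 = 0, s02 = NA_real_)
    s2_post <- s2
    df_total <- df
  }
  se <- sqrt(s2_post) * unscaled_se
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[tstat == 0] <- 1

  tab <- tibble::tibble(
    gene = rownames(expr),
    log2fc = unname(beta),
    t = unname(tstat),
    p = unname(p),
    p_adj = adjust_fdr(unname(p))
  )
  structure(
    list(
      table = tab, orientation = "IIIM - YM",
      prior_df = prior$df0, prior_var = prior$s02,
      residual_df = df, n_sv = ncol(X) - 2L
    ),
    class = "protoy_de"
  )
}

#' @export
print.protoy_de <- function(x, ...) {
  cat("Moderated differential-expression fit (", x$orientation, ")\n", sep = "")
  cat(
    nrow(x$table), "genes;", sum(x$table$p_adj < 0.05), "DE at FDR 0.05;",
    x$n_sv, "surrogate variables; prior df", format(x$prior_df, digits = 3), "\n"
  )
  print(x$table, n = 6)
  invisible(x)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior,
# using E[log s^2] = digamma(df/2) - log(df/2) + log s0^2 + digamma/trigamma
# identities for chi-square mixtures. Returns df0 = Inf (complete shrinkage
# to a common variance) when the observed spread of log s^2 is no larger
# than expected from sampling alone.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) {
    return(list(df0 = 0, s02 = mean(s2)))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(e) - trigamma(df / 2)
  if (is.na(ev) || ev <= 0) {
    df0 <- Inf
    s02 <- exp(mean(e))
  } else {
    df0 <- 2 * trigamma_inverse(ev)
    s02 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
  }
  list(df0 = df0, s02 = s02)
}

# Newton solve of trigamma(y) = x on y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone in rank and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}
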