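# Independent brute-force oracles used across tests. These deliberately use
# naive loops / exhaustive enumeration, not the package's vectorized code.

naive_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  w <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        w[i, j] <- 1
        next
      }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      denom <- min(k[i], k[j]) + 1 - a[i, j]
      w[i, j] <- if (denom == 0) 0 else (l + a[i, j]) / denom
    }
  }
  dimnames(w) <- dimnames(a)
  w
}

naive_kwithin <- function(adj, modules) {
  kw <- setNames(numeric(nrow(adj)), rownames(adj))
  mod <- setNames(modules$module, modules$gene)
  for (g in rownames(adj)) {
    if (mod[g] == "0") next
    for (h in rownames(adj)) {
      if (h != g && mod[h] == mod[g]) kw[g] <- kw[g] + adj[g, h]
    }
  }
  kw
}

naive_connection_scores <- function(adj, seeds, fc) {
  absF <- abs(setNames(fc$log2fc, fc$gene))
  out <- c()
  for (g in setdiff(rownames(adj), seeds)) {
    s <- 0
    for (j in seeds) s <- s + adj[g, j] * absF[j]
    out[g] <- s
  }
  out
}

# step-up definition of Benjamini-Hochberg, computed literally
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p-value,
# written with explicit binomial coefficients
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2]
  n2 <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  support <- max(0, k - n2):min(k, m)
  prob <- sapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  })
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group assignments
enumerate_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  ranks <- rank(all_v)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(all_v), n1)
  w_null <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
}

# classical two-sample regression t for one gene (textbook formula)
classical_t <- function(values, group) {
  f <- lm(values ~ group)
  summary(f)$coefficients[2, "t value"]
}

rand_adjacency <- function(n, seed) {
  set.seed(seed)
  r <- matrix(runif(n * n, -1, 1), n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(gene_ids(n), gene_ids(n))
  abs(r)^3
}

gene_ids <- function(n, prefix = "gene") {
  sprintf("%s_%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}
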