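planted_block_expr <- function(sizes, rho, n_samples, seed, n_noise = 0) {
  set.seed(seed)
  n <- sum(sizes) + n_noise
  expr <- matrix(rnorm(n * n_samples), n, n_samples,
    dimnames = list(gene_ids(n), sprintf("s%02d", seq_len(n_samples)))
  )
  loading <- sqrt(rho / (1 - rho))
  at <- 1L
  truth <- integer(n)
  for (b in seq_along(sizes)) {
    idx <- seq.int(at, length.out = sizes[b])
    truth[idx] <- b
    z <- rnorm(n_samples)
    expr[idx, ] <- expr[idx, ] + matrix(loading * z, sizes[b], n_samples, byrow = TRUE)
    at <- at + sizes[b]
  }
  list(expr = expr, truth = truth)
}

test_that("Pearson correlation matches the naive two-pass formula and flags degenerate input", {
  set.seed(3)
  expr <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(gene_ids(10), paste0("s", 1:8)))
  expr[2, ] <- expr[1, ] # identical genes
  r <- correlation_matrix(expr)
  expect_equal(r["gene_0001", "gene_0002"], 1)
  expr[3, ] <- -expr[1, ]
  r <- correlation_matrix(expr)
  expect_equal(r["gene_0001", "gene_0003"], -1)

  naive <- matrix(1, 10, 10)
  for (i in 1:10) {
    for (j in 1:10) {
      xi <- expr[i, ] - mean(expr[i, ])
      xj <- expr[j, ] - mean(expr[j, ])
      naive[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  diag(naive) <- 1
  expect_equal(unname(r), naive, tolerance = 1e-12)

  expect_error(correlation_matrix(expr[, 1:2]), "3 samples")
  expr[4, ] <- 5
  expect_warning(r2 <- correlation_matrix(expr), "zero-variance")
  expect_false("gene_0004" %in% rownames(r2))
})

test_that("soft-threshold adjacency is the unsigned power of the correlation", {
  expect_equal(unname(adjacency(matrix(c(1, 0.9, 0.9, 1), 2), 7)[1, 2]), 0.4783, tolerance = 1e-4)
  expect_equal(unname(adjacency(matrix(c(1, -0.9, -0.9, 1), 2), 7)[1, 2]), 0.4783, tolerance = 1e-4)
  expect_error(adjacency(diag(2), 0.5), "integer")

  set.seed(5)
  r <- cor(matrix(rnorm(60), 10, 6))
  dimnames(r) <- list(gene_ids(6), gene_ids(6))
  a <- adjacency(r, 5)
  naive <- abs(r)^5
  diag(naive) <- 1
  expect_equal(unname(a), unname(naive), tolerance = 1e-12, ignore_attr = TRUE)
  # unsigned: adjacency of corr equals adjacency of -corr
  negr <- -r
  diag(negr) <- 1
  expect_equal(unname(adjacency(negr, 5)), unname(a), tolerance = 1e-12)
})

test_that("soft-threshold selection finds a scale-free power and records the reference", {
  # approximately scale-free connectivity: hub-and-spoke latent structure
  set.seed(17)
  n <- 300
  n_samples <- 30
  hubs <- matrix(rnorm(5 * n_samples), 5, n_samples)
  expr <- matrix(rnorm(n * n_samples, sd = 1), n, n_samples,
    dimnames = list(gene_ids(n), sprintf("s%02d", 1:n_samples))
  )
  strength <- rexp(n, 1)
  for (i in seq_len(n)) {
    expr[i, ] <- expr[i, ] + strength[i] * hubs[sample.int(5, 1), ]
  }
  sft <- pick_soft_threshold(correlation_matrix(expr), 1:10)
  expect_true(7 %in% sft$fit$beta)
  expect_equal(sft$reference_beta, 7L)
  expect_gte(max(sft$fit$rsq, na.rm = TRUE), 0.8)
  expect_false(sft$warning_flag)

  # beta = 1 leaves |r| untouched
  r <- correlation_matrix(expr[1:20, ])
  expect_equal(unname(adjacency(r, 1)), unname(abs(r)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("topological overlap matches its closed form and the brute-force loop", {
  ones <- matrix(1, 3, 3, dimnames = list(gene_ids(3), gene_ids(3)))
  expect_equal(unname(topological_overlap(ones)), matrix(1, 3, 3))

  a <- rand_adjacency(6, seed = 8)
  a[1, -1] <- 0
  a[-1, 1] <- 0 # isolated gene
  w <- topological_overlap(a)
  expect_equal(unname(w[1, -1]), rep(0, 5))
  expect_equal(unname(w), unname(naive_tom(a)), tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w, t(w))

  bad <- a
  bad[2, 3] <- bad[3, 2] <- 1.5
  expect_error(topological_overlap(bad), "\\[0, 1\\]")
})

test_that("adjacency and TOM are equivariant under gene reordering", {
  a <- rand_adjacency(8, seed = 13)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  expect_equal(topological_overlap(a)[perm, perm], topological_overlap(a[perm, perm]),
    tolerance = 1e-12
  )
})

test_that("module detection recovers planted blocks and honours the size filter", {
  ari <- vapply(1:3, function(s) {
    pb <- planted_block_expr(c(50, 50), rho = 0.8, n_samples = 20, seed = s, n_noise = 20)
    tom <- topological_overlap(adjacency(correlation_matrix(pb$expr), 6))
    mods <- detect_modules(tom, pb$expr, min_size = 30)
    keep <- pb$truth > 0
    mclust::adjustedRandIndex(mods$module[keep], pb$truth[keep])
  }, numeric(1))
  expect_true(all(ari > 0.9))

  # a 10-gene block cannot survive min_size = 30
  pb <- planted_block_expr(10, rho = 0.9, n_samples = 20, seed = 4, n_noise = 40)
  tom <- topological_overlap(adjacency(correlation_matrix(pb$expr), 6))
  mods <- detect_modules(tom, pb$expr, min_size = 30)
  expect_true(all(mods$module[pb$truth == 1] == "0"))

  # detection is deterministic
  mods2 <- detect_modules(tom, pb$expr, min_size = 30)
  expect_identical(mods, mods2)
})

test_that("blocks driven by one latent factor merge at the eigengene threshold", {
  set.seed(9)
  n_samples <- 20
  z <- rnorm(n_samples)
  expr <- matrix(rnorm(80 * n_samples, sd = 0.6), 80, n_samples,
    dimnames = list(gene_ids(80), sprintf("s%02d", 1:n_samples))
  )
  expr[1:40, ] <- expr[1:40, ] + matrix(z, 40, n_samples, byrow = TRUE)
  expr[41:80, ] <- expr[41:80, ] + matrix(z, 40, n_samples, byrow = TRUE)
  tom <- topological_overlap(adjacency(correlation_matrix(expr), 6))
  mods <- detect_modules(tom, expr, min_size = 30, merge_threshold = 0.2)
  assigned <- mods$module[mods$module != "0"]
  expect_equal(length(unique(assigned)), 1)
})

test_that("eigengenes are the first principal component of the standardized module", {
  set.seed(15)
  n_samples <- 12
  common <- rnorm(n_samples)
  expr <- matrix(rep(common, each = 6), 6, n_samples,
    dimnames = list(gene_ids(6), paste0("s", 1:n_samples))
  )
  mods <- tibble::tibble(gene = rownames(expr), module = "1")
  me <- module_eigengenes(expr + rnorm(length(expr), sd = 1e-8), mods)
  std <- (common - mean(common)) / sd(common)
  expect_equal(abs(cor(me[, 1], std)), 1, tolerance = 1e-6)
  expect_equal(sum(me[, 1]^2), 1, tolerance = 1e-8)
  expect_gte(cor(me[, 1], common), 0)

  # PC1 optimality: no random unit vector explains more variance
  expr2 <- matrix(rnorm(8 * n_samples), 8, n_samples,
    dimnames = list(gene_ids(8), paste0("s", 1:n_samples))
  )
  z <- t(scale(t(expr2)))
  me2 <- module_eigengenes(expr2, tibble::tibble(gene = rownames(expr2), module = "1"))[, 1]
  var_me <- sum((z %*% me2)^2)
  for (i in 1:100) {
    v <- rnorm(n_samples)
    v <- v / sqrt(sum(v^2))
    expect_lte(sum((z %*% v)^2), var_me + 1e-8)
  }

  # matches a brute-force eigendecomposition of the standardized covariance
  ev <- eigen(crossprod(z))
  v1 <- ev$vectors[, 1]
  expect_equal(abs(sum(me2 * v1)), 1, tolerance = 1e-8)

  const <- matrix(3, 4, n_samples, dimnames = list(gene_ids(4), paste0("s", 1:n_samples)))
  expect_error(
    module_eigengenes(const, tibble::tibble(gene = rownames(const), module = "1")),
    "zero-variance"
  )
})

test_that("module-trait association flags the trait-driven module", {
  trait <- rep(c(0, 1), each = 10)
  me <- cbind(
    ME1 = (trait - mean(trait)) / sqrt(sum((trait - mean(trait))^2)),
    ME2 = rnorm(20)
  )
  rownames(me) <- paste0("s", 1:20)
  res <- module_trait_association(me, trait)
  expect_equal(res$r[res$module == "1"], 1, tolerance = 1e-10)
  expect_lt(res$p[res$module == "1"], 1e-12)
  expect_error(module_trait_association(me, rep(1, 20)), "constant")

  hits <- vapply(1:20, function(s) {
    pb <- planted_block_expr(c(40, 40), rho = 0.6, n_samples = 24, seed = s + 100, n_noise = 10)
    trait <- rep(c(0, 1), each = 12)
    pb$expr[pb$truth == 1, ] <- pb$expr[pb$truth == 1, ] +
      matrix(1.5 * trait, 40, 24, byrow = TRUE)
    mods <- tibble::tibble(gene = rownames(pb$expr), module = as.character(pb$truth))
    me <- module_eigengenes(pb$expr, mods)
    res <- module_trait_association(me, trait)
    res$module[which.min(res$p_adj)] == "1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("intramodular connectivity matches the double loop and ignores unassigned genes", {
  ones <- matrix(1, 3, 3, dimnames = list(gene_ids(3), gene_ids(3)))
  mods <- tibble::tibble(gene = gene_ids(3), module = "1")
  expect_equal(intramodular_connectivity(ones, mods)$k_within, rep(2, 3))

  mods$module <- c("1", "2", "0")
  kw <- intramodular_connectivity(ones, mods)
  expect_equal(kw$k_within, c(0, 0, 0)) # singletons and unassigned

  a <- rand_adjacency(10, seed = 21)
  mods <- tibble::tibble(
    gene = rownames(a),
    module = rep(c("1", "2", "0"), c(4, 4, 2))
  )
  kw <- intramodular_connectivity(a, mods)
  expect_equal(setNames(kw$k_within, kw$gene), naive_kwithin(a, mods), tolerance = 1e-12)

  # hub ranking unchanged by adding unassigned genes
  sub <- a[1:8, 1:8]
  kw_sub <- intramodular_connectivity(sub, mods[1:8, ])
  rank_full <- order(-kw$k_within[1:8])
  rank_sub <- order(-kw_sub$k_within)
  expect_identical(rank_full, rank_sub)
})
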