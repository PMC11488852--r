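make_calls <- function(...) {
  tibble::as_tibble(data.frame(...))
}

sep_depth_table <- function(iiim_fpm_high = c(12, 8, 30, 5), iiim_fpm_low = c(0.3, 0.5, 0.2, 0.4),
                            ym_fpm = c(2.1, 3.2, 1.1, 2.6), lib = 1e7, pos = 1000L) {
  # one site, complete separation between the IIIM allele and everything else
  dplyr::bind_rows(
    tibble::tibble(
      scaffold = "sc1", pos = pos, allele = "IIIM",
      group = paste0("IIIM_g", 1:4), genotype = "IIIM",
      depth = iiim_fpm_high * lib / 1e6, library_size = lib
    ),
    tibble::tibble(
      scaffold = "sc1", pos = pos, allele = "III",
      group = paste0("IIIM_g", 1:4), genotype = "IIIM",
      depth = iiim_fpm_low * lib / 1e6, library_size = lib
    ),
    tibble::tibble(
      scaffold = "sc1", pos = pos, allele = "III",
      group = paste0("YM_g", 1:4), genotype = "YM",
      depth = ym_fpm * lib / 1e6, library_size = lib
    )
  )
}

test_that("diagnostic SNP selection keeps het-in-IIIM / hom-in-YM sites and assigns alleles", {
  calls <- dplyr::bind_rows(
    # diagnostic: A/G het in IIIM, G/G hom in YM -> IIIM allele is A
    make_calls(
      scaffold = "sc1", pos = 100L,
      group = c(paste0("IIIM_g", 1:4), paste0("YM_g", 1:4)),
      genotype = rep(c("IIIM", "YM"), each = 4),
      allele_a = c(rep("A", 4), rep("G", 4)),
      allele_b = rep("G", 8)
    ),
    # het in both genotypes: rejected
    make_calls(
      scaffold = "sc1", pos = 200L,
      group = c(paste0("IIIM_g", 1:4), paste0("YM_g", 1:4)),
      genotype = rep(c("IIIM", "YM"), each = 4),
      allele_a = rep("A", 8), allele_b = rep("G", 8)
    ),
    # hom in IIIM: rejected
    make_calls(
      scaffold = "sc1", pos = 300L,
      group = c(paste0("IIIM_g", 1:4), paste0("YM_g", 1:4)),
      genotype = rep(c("IIIM", "YM"), each = 4),
      allele_a = rep("T", 8), allele_b = rep("T", 8)
    )
  )
  sel <- select_diagnostic_snps(calls)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$pos, 100L)
  expect_equal(sel$allele_iiim, "A")
  expect_equal(sel$allele_iii, "G")

  # conflicting YM homozygotes across groups: dropped with a warning
  conflict <- make_calls(
    scaffold = "sc1", pos = 400L,
    group = c(paste0("IIIM_g", 1:4), paste0("YM_g", 1:4)),
    genotype = rep(c("IIIM", "YM"), each = 4),
    allele_a = c(rep("A", 4), "G", "G", "T", "T"),
    allele_b = c(rep("G", 4), "G", "G", "T", "T")
  )
  expect_warning(sel2 <- select_diagnostic_snps(dplyr::bind_rows(calls, conflict)), "conflicting")
  expect_equal(sel2$pos, 100L)

  # 20-site fixture against a hand filter: only even multiples of 100 below 1100
  set.seed(6)
  many <- purrr::map_dfr(1:20, function(i) {
    diagnostic <- i %% 2 == 0 && i <= 10
    make_calls(
      scaffold = "sc2", pos = i * 100L,
      group = c(paste0("IIIM_g", 1:4), paste0("YM_g", 1:4)),
      genotype = rep(c("IIIM", "YM"), each = 4),
      allele_a = if (diagnostic) c(rep("C", 4), rep("T", 4)) else rep("T", 8),
      allele_b = rep("T", 8)
    )
  })
  sel3 <- select_diagnostic_snps(many)
  expect_equal(sort(sel3$pos), c(200L, 400L, 600L, 800L, 1000L))
})

test_that("FPM normalization is exact and scale-invariant", {
  tbl <- tibble::tibble(
    group = "g1", depth = 5, library_size = 1e7
  )
  expect_equal(normalize_depth_fpm(tbl)$fpm, 0.5)

  set.seed(4)
  tbl2 <- tibble::tibble(
    group = rep(paste0("g", 1:4), each = 5),
    depth = rpois(20, 30),
    library_size = rep(c(8e6, 9e6, 1.1e7, 1.2e7), each = 5)
  )
  fpm <- normalize_depth_fpm(tbl2)$fpm
  expect_equal(fpm, tbl2$depth / tbl2$library_size * 1e6, tolerance = 1e-12)
  doubled <- dplyr::mutate(tbl2, depth = depth * 2, library_size = library_size * 2)
  expect_equal(normalize_depth_fpm(doubled)$fpm, fpm, tolerance = 1e-12)

  bad <- dplyr::mutate(tbl2, library_size = ifelse(group == "g2", 0, library_size))
  expect_error(normalize_depth_fpm(bad), "g2")
})

test_that("complete separation of 4 vs 4 groups reproduces the characteristic p-values", {
  tbl <- sep_depth_table()
  res <- compare_alleles(tbl)
  # normal approximation without continuity correction: 2 * Phi(-8 / sqrt(12))
  p_expected <- 2 * pnorm(-8 / sqrt(12))
  expect_equal(round(p_expected, 3), 0.021)
  iiim_iii <- res$p[res$comparison == "IIIM-III"]
  expect_equal(iiim_iii, p_expected, tolerance = 1e-10)
  expect_equal(round(iiim_iii, 3), 0.021)
  expect_true(all(res$significant))

  # the exact method gives the enumeration value 2/70
  res_exact <- compare_alleles(tbl, method = "exact")
  expect_equal(res_exact$p[res_exact$comparison == "IIIM-III"], 2 / 70, tolerance = 1e-12)
})

test_that("rank-sum comparisons behave under ties, label swaps, and library rescaling", {
  # identical values in all groups: centered statistic, p ~ 1
  flat <- sep_depth_table(
    iiim_fpm_high = rep(2, 4), iiim_fpm_low = rep(2, 4), ym_fpm = rep(2, 4)
  )
  res <- compare_alleles(flat)
  expect_true(all(res$p >= 0.99))

  # antisymmetry of IIIM-III under allele label swap: same p
  tbl <- sep_depth_table()
  swapped <- dplyr::mutate(tbl, allele = dplyr::case_when(
    genotype == "IIIM" & allele == "IIIM" ~ "III",
    genotype == "IIIM" & allele == "III" ~ "IIIM",
    TRUE ~ allele
  ))
  r1 <- compare_alleles(tbl)
  r2 <- compare_alleles(swapped)
  expect_equal(
    r1$p[r1$comparison == "IIIM-III"],
    r2$p[r2$comparison == "IIIM-III"],
    tolerance = 1e-12
  )
  # statistic flips across the tie-free range [0, 16]
  expect_equal(
    r1$statistic[r1$comparison == "IIIM-III"],
    16 - r2$statistic[r2$comparison == "IIIM-III"]
  )

  # common rescaling of all library sizes leaves every p unchanged
  rescaled <- dplyr::mutate(tbl, library_size = library_size * 3.7)
  r3 <- compare_alleles(rescaled)
  expect_equal(r1$p, r3$p, tolerance = 1e-12)

  # exact method equals full permutation enumeration for n <= 6 per group
  set.seed(123)
  for (i in 1:5) {
    x <- round(runif(4) * 50) + runif(4) # no ties w.p. 1
    y <- round(runif(6) * 50) + runif(6)
    p_pkg <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, enumerate_ranksum_p(x, y), tolerance = 1e-12)
    one_site <- dplyr::bind_rows(
      tibble::tibble(
        scaffold = "sc", pos = 1L, allele = "IIIM",
        group = paste0("IIIM_g", 1:4), genotype = "IIIM",
        depth = x * 10, library_size = 1e7
      ),
      tibble::tibble(
        scaffold = "sc", pos = 1L, allele = "III",
        group = paste0("IIIM_g", 1:4), genotype = "IIIM",
        depth = y[1:4] * 10, library_size = 1e7
      ),
      tibble::tibble(
        scaffold = "sc", pos = 1L, allele = "III",
        group = paste0("YM_g", 1:4), genotype = "YM",
        depth = y[1:4] * 10, library_size = 1e7
      )
    )
    r <- suppressWarnings(compare_alleles(one_site, method = "exact"))
    expect_equal(
      r$p[r$comparison == "IIIM-III"],
      enumerate_ranksum_p(x * 10, y[1:4] * 10),
      tolerance = 1e-12
    )
  }
})

test_that("monoallelic flagging requires strict zero III depth with positive IIIM depth", {
  tbl <- sep_depth_table(iiim_fpm_low = c(0, 0, 0, 0))
  expect_true(flag_monoallelic(tbl)$monoallelic)

  one_read <- sep_depth_table(iiim_fpm_low = c(0, 0.1, 0, 0))
  expect_false(flag_monoallelic(one_read)$monoallelic)

  no_iiim <- sep_depth_table(iiim_fpm_high = c(12, 0, 30, 5), iiim_fpm_low = c(0, 0, 0, 0))
  expect_false(flag_monoallelic(no_iiim)$monoallelic)

  # flags are joined onto the comparison report
  res <- compare_alleles(tbl)
  expect_true(all(res$monoallelic))
})
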