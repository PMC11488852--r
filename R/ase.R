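#' Select diagnostic SNPs separating III^M and III chromosome alleles
#'
#' A site is diagnostic when it is heterozygous in every III^M group and
#' homozygous, for a common allele, in every Y^M group. Because Y^M males
#' carry two standard third-chromosome (III) alleles, their shared allele is
#' assigned to the III chromosome; the heterozygous allele absent from Y^M
#' genotypes is assigned to the III^M chromosome. Sites where Y^M groups
#' disagree on the homozygous allele are dropped (reported in the
#' `dropped` attribute).
#'
#' @param genotype_calls Data frame with columns `scaffold`, `pos`,
#'   `group`, `genotype` (`"IIIM"` or `"YM"`), `allele_a`, `allele_b`
#'   (the two called alleles; equal when homozygous).
#'
#' @return Tibble of selected sites with columns `scaffold`, `pos`,
#'   `allele_iiim`, `allele_iii`.
#' @export
select_diagnostic_snps <- function(genotype_calls) {
  calls <- tibble::as_tibble(genotype_calls)
  stopifnot(all(c("scaffold", "pos", "group", "genotype", "allele_a", "allele_b") %in% names(calls)))
  dropped <- character()
  out <- calls |>
    dplyr::group_by(.data$scaffold, .data$pos) |>
    dplyr::group_map(function(site, key) {
      iiim <- site[site$genotype == "IIIM", ]
      ym <- site[site$genotype == "YM", ]
      if (!nrow(iiim) || !nrow(ym)) return(NULL)
      if (!all(iiim$allele_a != iiim$allele_b)) return(NULL) # het in all IIIM
      if (!all(ym$allele_a == ym$allele_b)) return(NULL) # hom in all YM
      ym_allele <- unique(ym$allele_a)
      if (length(ym_allele) != 1) {
        dropped <<- c(dropped, sprintf("%s:%d", key$scaffold, key$pos))
        return(NULL)
      }
      het <- unique(c(iiim$allele_a, iiim$allele_b))
      iiim_allele <- setdiff(het, ym_allele)
      # the heterozygote must carry the YM (III) allele plus exactly one other
      if (length(iiim_allele) != 1 || !ym_allele %in% het) return(NULL)
      tibble::tibble(
        scaffold = key$scaffold, pos = key$pos,
        allele_iiim = iiim_allele, allele_iii = ym_allele
      )
    }) |>
    dplyr::bind_rows()
  if (length(dropped)) {
    warn(paste0("Dropped site(s) with conflicting Y^M homozygous alleles: ", paste(dropped, collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Normalize allele read depths to fragments per million (FPM)
#'
#' `fpm = depth / library_size * 1e6`, where `library_size` is the total
#' number of mapped reads for the strain-by-batch group. Raw depths are
#' retained.
#'
#' @param table Data frame with at least columns `depth`, `library_size`,
#'   and `group`.
#' @return The input as a tibble with an `fpm` column.
#' @export
normalize_depth_fpm <- function(table) {
  tbl <- tibble::as_tibble(table)
  stopifnot(all(c("depth", "library_size", "group") %in% names(tbl)))
  bad <- tbl$library_size <= 0
  if (any(bad)) {
    abort(paste0(
      "Zero or negative library size for group(s): ",
      paste(unique(tbl$group[bad]), collapse = ", ")
    ))
  }
  dplyr::mutate(tbl, fpm = .data$depth / .data$library_size * 1e6)
}

#' Rank-sum comparisons of allele-specific expression
#'
#' At each diagnostic site, three Wilcoxon rank-sum comparisons of
#' FPM-normalized read depths are made:
#' \describe{
#'   \item{IIIM-III}{III^M allele vs III allele within III^M male groups}
#'   \item{IIIM-YM}{III^M allele in III^M males vs both III alleles
#'     (the total III depth) in Y^M males}
#'   \item{III-YM}{III allele in III^M males vs Y^M males}
#' }
#' The default method is the normal approximation without continuity
#' correction, which for complete separation of two groups of four gives
#' p = 0.021; `method = "exact"` enumerates the rank-sum distribution and
#' is recommended for new data (see the methods vignette).
#'
#' @param table Allele depth table with columns `scaffold`, `pos`,
#'   `allele`, `group`, `genotype`, `depth`, `library_size`, and `fpm`
#'   (add it with [normalize_depth_fpm()]).
#' @param method `"normal_approx"` (default) or `"exact"`.
#' @param alpha Significance threshold for the `significant` flag.
#'
#' @return Tibble, one row per site x comparison, with columns `scaffold`,
#'   `pos`, `comparison`, `statistic` (the rank-sum W of the first group),
#'   `p`, `significant`; plus a `monoallelic` column per site from
#'   [flag_monoallelic()].
#' @export
compare_alleles <- function(table, method = c("normal_approx", "exact"), alpha = 0.05) {
  method <- match.arg(method)
  tbl <- tibble::as_tibble(table)
  if (!"fpm" %in% names(tbl)) tbl <- normalize_depth_fpm(tbl)
  n_iiim <- length(unique(tbl$group[tbl$genotype == "IIIM"]))
  n_ym <- length(unique(tbl$group[tbl$genotype == "YM"]))
  if (n_iiim != 4 || n_ym != 4) {
    warn(sprintf("Group design is %d III^M + %d Y^M (expected 4 + 4).", n_iiim, n_ym))
  }
  mono <- flag_monoallelic(tbl)

  res <- tbl |>
    dplyr::group_by(.data$scaffold, .data$pos) |>
    dplyr::group_map(function(site, key) {
      x_iiim <- site$fpm[site$genotype == "IIIM" & site$allele == "IIIM"]
      x_iii <- site$fpm[site$genotype == "IIIM" & site$allele == "III"]
      x_ym <- site$fpm[site$genotype == "YM" & site$allele == "III"]
      cmp <- list(
        `IIIM-III` = list(x_iiim, x_iii),
        `IIIM-YM` = list(x_iiim, x_ym),
        `III-YM` = list(x_iii, x_ym)
      )
      purrr::imap_dfr(cmp, function(pair, name) {
        if (!length(pair[[1]]) || !length(pair[[2]])) {
          warn(sprintf("Site %s:%d skipped for %s: missing depths.", key$scaffold, key$pos, name))
          return(NULL)
        }
        wt <- suppressWarnings(wilcox.test(
          pair[[1]], pair[[2]],
          exact = method == "exact", correct = FALSE
        ))
        p <- wt$p.value
        if (is.nan(p)) p <- 1 # zero-variance rank-sum (all values tied)
        tibble::tibble(
          scaffold = key$scaffold, pos = key$pos, comparison = name,
          statistic = unname(wt$statistic), p = p,
          significant = p < alpha
        )
      })
    }) |>
    dplyr::bind_rows()
  dplyr::left_join(res, mono, by = c("scaffold", "pos"))
}

#' Flag candidate monoallelic expression
#'
#' A site is flagged when the III-allele raw depth is exactly zero in every
#' III^M group while the III^M-allele depth is positive in every III^M
#' group: all reads map to the III^M allele, the pattern suggestive of
#' monoallelic expression of the III^M allele.
#'
#' @param table Allele depth table (columns `scaffold`, `pos`, `allele`,
#'   `genotype`, `depth`).
#' @return Tibble with columns `scaffold`, `pos`, `monoallelic`.
#' @export
flag_monoallelic <- function(table) {
  tibble::as_tibble(table) |>
    dplyr::filter(.data$genotype == "IIIM") |>
    dplyr::group_by(.data$scaffold, .data$pos) |>
    dplyr::summarise(
      monoallelic = all(.data$depth[.data$allele == "III"] == 0) &&
        all(.data$depth[.data$allele == "IIIM"] > 0) &&
        any(.data$allele == "IIIM"),
      .groups = "drop"
    )
}
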