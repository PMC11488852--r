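#' Volcano plot of differential expression
#'
#' @param de A `protoy_de` object or tidy DE table.
#' @param fdr FDR threshold used to highlight genes.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, fdr = 0.05) {
  tab <- de_table(de)
  tab$status <- ifelse(tab$p_adj < fdr,
    ifelse(tab$log2fc > 0, "up in IIIM", "up in YM"), "not DE"
  )
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, -log10(.data$p), colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "not DE" = "grey60", "up in IIIM" = "#d95f02", "up in YM" = "#1b9e77"
    )) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold-change (III"^M * " - Y"^M * ")"),
      y = expression(-log[10] ~ p), colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Scale-free fit diagnostics for soft-threshold selection
#'
#' @param object A `protoy_sft` object.
#' @param ... Unused.
#' @return A ggplot object: fit R-squared and mean connectivity per
#'   candidate power.
#' @export
autoplot.protoy_sft <- function(object, ...) {
  long <- tidyr::pivot_longer(object$fit, c("rsq", "mean_k"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric,
    levels = c("rsq", "mean_k"),
    labels = c("scale-free fit R\u00b2", "mean connectivity")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$beta, .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$beta, linetype = 2, colour = "#d95f02") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(beta), y = NULL) +
    ggplot2::theme_minimal()
}

#' Allele-specific expression profile across diagnostic sites
#'
#' Mirrors the per-site read-depth panels of an ASE figure: FPM of the
#' III^M and III alleles in III^M males and the III alleles in Y^M males,
#' by scaffold position.
#'
#' @param depths Allele depth table with an `fpm` column (see
#'   [normalize_depth_fpm()]).
#' @return A ggplot object.
#' @export
plot_ase <- function(depths) {
  tbl <- tibble::as_tibble(depths)
  if (!"fpm" %in% names(tbl)) tbl <- normalize_depth_fpm(tbl)
  tbl$series <- paste0(tbl$allele, " allele (", tbl$genotype, " males)")
  means <- tbl |>
    dplyr::group_by(.data$pos, .data$series) |>
    dplyr::summarise(fpm = mean(.data$fpm), .groups = "drop")
  ggplot2::ggplot(tbl, ggplot2::aes(.data$pos, .data$fpm, colour = .data$series)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = means) +
    ggplot2::scale_colour_manual(values = c(
      "IIIM allele (IIIM males)" = "salmon",
      "III allele (IIIM males)" = "turquoise3",
      "III allele (YM males)" = "black"
    )) +
    ggplot2::labs(
      x = "scaffold position (bp)", y = "fragments per million (FPM)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for copulation latency
#'
#' @param records Latency table with columns `latency`, `censored`, and a
#'   grouping column.
#' @param group Name of the grouping column (default `"genotype"`).
#' @return A ggplot object showing the proportion not yet mated over time.
#' @export
plot_latency_curves <- function(records, group = "genotype") {
  tbl <- tibble::as_tibble(records)
  sf <- survival::survfit(
    as.formula(paste("survival::Surv(latency, !censored) ~", group)),
    data = tbl
  )
  strata <- rep(names(sf$strata), sf$strata)
  df <- tibble::tibble(
    time = sf$time, surv = sf$surv,
    group = sub(".*=", "", strata)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "minutes", y = "proportion not yet mated", colour = group) +
    ggplot2::theme_minimal()
}
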