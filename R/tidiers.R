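#' Tidy differential-expression results
#'
#' @param x A `protoy_de` object.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `log2fc`, `t`, `p`, `p_adj`.
#' @export
tidy.protoy_de <- function(x, ...) x$table

#' @rdname tidy.protoy_de
#' @export
glance.protoy_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_de = sum(x$table$p_adj < 0.05),
    n_sv = x$n_sv,
    prior_df = x$prior_df,
    residual_df = x$residual_df,
    orientation = x$orientation
  )
}

#' Tidy a Cox latency fit
#'
#' @param x A `protoy_cox` object.
#' @param ... Unused.
#' @return Coefficient tibble with hazard ratios and Wald 95% intervals.
#' @export
tidy.protoy_cox <- function(x, ...) x$coefficients

#' @rdname tidy.protoy_cox
#' @export
glance.protoy_cox <- function(x, ...) {
  tibble::tibble(
    n = x$fit$n,
    n_events = x$fit$nevent,
    loglik = x$fit$loglik[length(x$fit$loglik)],
    concordance = unname(x$fit$concordance["concordance"]),
    ties = x$ties
  )
}

#' Tidy a competitive courtship logistic fit
#'
#' @param x A `protoy_logit` object.
#' @param ... Unused.
#' @return The type-II likelihood-ratio test table.
#' @export
tidy.protoy_logit <- function(x, ...) x$tests

#' @rdname tidy.protoy_logit
#' @export
glance.protoy_logit <- function(x, ...) {
  tibble::tibble(
    n = length(x$fit$y),
    loglik = as.numeric(logLik(x$fit)),
    separation = x$separation,
    contest = x$contest
  )
}

#' Tidy a Fisher's exact test
#'
#' @param x A `protoy_fisher` object.
#' @param ... Unused.
#' @return One-row tibble with cell counts, odds ratio, and p-value.
#' @export
tidy.protoy_fisher <- function(x, ...) {
  tibble::tibble(
    a = x$table[1, 1], b = x$table[1, 2],
    c = x$table[2, 1], d = x$table[2, 2],
    odds_ratio = x$odds_ratio, p = x$p, degenerate = x$degenerate
  )
}

#' Tidy a soft-threshold selection
#'
#' @param x A `protoy_sft` object.
#' @param ... Unused.
#' @return The per-candidate fit table with a `chosen` flag.
#' @export
tidy.protoy_sft <- function(x, ...) {
  dplyr::mutate(x$fit, chosen = .data$beta == x$beta)
}
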