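#' Accumulated degree days
#'
#' `ADD = (T_D - T_t) * d`: physiological age as degree days above the
#' threshold developmental temperature. The default threshold of 12.4
#' degrees C is the estimated house fly developmental threshold; for
#' D. melanogaster a threshold of 10 degrees C is conventional.
#'
#' @param t_dev Developmental temperature(s), degrees C.
#' @param days Days of development (vectorized with `t_dev`).
#' @param t_threshold Threshold developmental temperature, degrees C.
#' @return Numeric vector of degree days. A warning is raised when any
#'   value is negative (development below threshold).
#' @examples
#' accumulated_degree_days(18, 6) # 33.6 dd
#' accumulated_degree_days(29, 7) # 116.2 dd
#' @export
accumulated_degree_days <- function(t_dev, days, t_threshold = 12.4) {
  if (any(days < 0)) abort("`days` must be non-negative.")
  dd <- (t_dev - t_threshold) * days
  if (any(dd < 0)) warn("Negative degree days: development below the threshold temperature.")
  dd
}

#' Degree-day table
#'
#' Tidy wrapper over [accumulated_degree_days()] for a table of rearing
#' conditions.
#'
#' @param conditions Data frame with columns `t_dev`, `days`, and
#'   optionally `t_threshold` (default 12.4).
#' @return The input tibble with a `degree_days` column.
#' @export
degree_day_table <- function(conditions) {
  tbl <- tibble::as_tibble(conditions)
  stopifnot(all(c("t_dev", "days") %in% names(tbl)))
  if (!"t_threshold" %in% names(tbl)) tbl$t_threshold <- 12.4
  dplyr::mutate(tbl, degree_days = accumulated_degree_days(.data$t_dev, .data$days, .data$t_threshold))
}

#' Two-sample Z-test of proportions
#'
#' Pooled-variance z statistic without continuity correction. With
#' `alternative = "one_sided"` the p-value is the tail probability in the
#' direction of the observed difference.
#'
#' @param x1,n1 Successes and trials in arm 1.
#' @param x2,n2 Successes and trials in arm 2.
#' @param alternative `"two_sided"` (default) or `"one_sided"`.
#' @return Tibble with columns `z`, `p`, `p1`, `p2`.
#' @export
proportion_ztest <- function(x1, n1, x2, n2, alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) abort("Both arms must have at least one trial.")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) abort("Counts must satisfy 0 <= x <= n.")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- if (alternative == "two_sided") 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  tibble::tibble(z = z, p = min(p, 1), p1 = p1, p2 = p2)
}

#' Logistic model for competitive courtship outcomes
#'
#' Fits the competitive-assay models: for genotype contests,
#' `winner_is_IIIM ~ blue_genotype + temperature + blue_genotype:temperature
#' + batch`, and for temperature contests (same genotype, different rearing
#' temperatures), `winner_is_29C ~ genotype + blue_temperature +
#' genotype:blue_temperature + batch`. Batch enters as fixed-effect dummy
#' coding (a deliberate approximation of the random-batch formulation; see
#' the methods vignette), and is dropped with a warning when only one batch
#' is present. Type-II likelihood-ratio chi-square tests are computed for
#' each fixed effect: main effects are tested between nested models without
#' the interaction, and the interaction against the full model.
#'
#' @param trials Data frame of competitive trials. For
#'   `contest = "genotype"`: columns `winner` (`"IIIM"`/`"YM"`),
#'   `blue_genotype`, `temperature`, `batch`. For
#'   `contest = "temperature"`: columns `winner` (winning male's rearing
#'   temperature), `genotype`, `blue_temperature`, `batch`.
#' @param contest `"genotype"` or `"temperature"`.
#' @return Object of class `protoy_logit` with elements `fit` (the full
#'   `glm`), `tests` (tibble: `term`, `chisq`, `df`, `p`), and
#'   `separation` (logical).
#' @export
fit_competitive_model <- function(trials, contest = c("genotype", "temperature")) {
  contest <- match.arg(contest)
  tbl <- tibble::as_tibble(trials)
  if (contest == "genotype") {
    stopifnot(all(c("winner", "blue_genotype", "temperature", "batch") %in% names(tbl)))
    tbl$outcome <- as.integer(tbl$winner == "IIIM")
    t1 <- "blue_genotype"
    t2 <- "temperature"
  } else {
    stopifnot(all(c("winner", "genotype", "blue_temperature", "batch") %in% names(tbl)))
    lv <- sort(unique(as.character(tbl$winner)))
    tbl$outcome <- as.integer(as.character(tbl$winner) == lv[length(lv)])
    t1 <- "genotype"
    t2 <- "blue_temperature"
  }
  if (length(unique(tbl$outcome)) < 2) abort("Both outcome labels must be present.")
  for (v in c(t1, t2, "batch")) tbl[[v]] <- factor(tbl[[v]])
  has_batch <- nlevels(tbl$batch) > 1
  if (!has_batch) warn("Single batch: batch term dropped from the model.")

  base_terms <- c(t1, t2, if (has_batch) "batch")
  form <- function(terms) {
    as.formula(paste("outcome ~", paste(terms, collapse = " + ")))
  }
  inter <- paste0(t1, ":", t2)
  full <- glm(form(c(base_terms, inter)), family = binomial(), data = tbl)
  separation <- !full$converged || any(abs(full$coefficients) > 15, na.rm = TRUE)
  if (separation) {
    warn("Possible complete separation detected; coefficients from a weakly ridge-penalized fit.")
    full$coefficients <- ridge_logit(model.matrix(form(c(base_terms, inter)), tbl), tbl$outcome)
  }
  no_inter <- glm(form(base_terms), family = binomial(), data = tbl)
  drop1m <- glm(form(setdiff(base_terms, t1)), family = binomial(), data = tbl)
  drop2m <- glm(form(setdiff(base_terms, t2)), family = binomial(), data = tbl)

  lr <- function(fullm, redm) {
    chisq <- as.numeric(2 * (logLik(fullm) - logLik(redm)))
    df <- attr(logLik(fullm), "df") - attr(logLik(redm), "df")
    tibble::tibble(chisq = max(chisq, 0), df = df, p = pchisq(max(chisq, 0), df, lower.tail = FALSE))
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(lr(no_inter, drop1m), term = t1, .before = 1),
    dplyr::mutate(lr(no_inter, drop2m), term = t2, .before = 1),
    dplyr::mutate(lr(full, no_inter), term = inter, .before = 1)
  )
  structure(
    list(fit = full, tests = tests, separation = separation, contest = contest),
    class = "protoy_logit"
  )
}

# weakly ridge-penalized logistic regression by Newton iteration; used only
# as a fallback under complete separation (penalty keeps coefficients finite)
ridge_logit <- function(X, y, lambda = 1e-2, max_iter = 100) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  setNames(drop(beta), colnames(X))
}

#' @export
print.protoy_logit <- function(x, ...) {
  cat("Competitive courtship logistic model (", x$contest, " contest)\n", sep = "")
  if (x$separation) cat("NOTE: separation detected; penalized coefficients.\n")
  print(x$tests)
  invisible(x)
}

#' Cox proportional hazards model for copulation latency
#'
#' Fits a Cox model to right-censored copulation latencies with Efron tie
#' handling by default (latencies observed on a 10-minute grid are heavily
#' tied). Reports per-covariate hazard ratios with Wald 95% confidence
#' intervals and per-effect analysis-of-deviance (type II likelihood-ratio)
#' chi-square tests.
#'
#' @param records Data frame with columns `latency` (minutes), `censored`
#'   (logical), and the covariates.
#' @param covariates Character vector of model terms (may include
#'   interactions, e.g. `c("genotype", "temperature",
#'   "genotype:temperature", "batch")`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `protoy_cox` with elements `fit` (the `coxph`
#'   fit), `coefficients` (tibble: `term`, `estimate`, `hr`, `conf_low`,
#'   `conf_high`, `p`), and `tests` (type-II chi-square tibble).
#' @export
fit_cox_latency <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  tbl <- tibble::as_tibble(records)
  stopifnot(all(c("latency", "censored") %in% names(tbl)))
  if (!any(!tbl$censored)) abort("No uncensored events; the Cox model cannot be fit.")
  if ("genotype" %in% names(tbl) && all(tbl$genotype %in% c("YM", "IIIM"))) {
    # III^M vs Y^M orientation: hazard ratio > 1 means III^M mates faster
    tbl$genotype <- factor(tbl$genotype, levels = c("YM", "IIIM"))
  }
  form <- as.formula(paste(
    "survival::Surv(latency, !censored) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(form, data = tbl, ties = ties)
  if (any(is.na(fit$coefficients))) {
    abort("Cox model did not identify all coefficients (rank deficiency or non-convergence).")
  }
  est <- fit$coefficients
  se <- sqrt(diag(fit$var))
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    hr = exp(unname(est)),
    conf_low = exp(unname(est - qnorm(0.975) * se)),
    conf_high = exp(unname(est + qnorm(0.975) * se)),
    p = 2 * pnorm(-abs(unname(est) / se))
  )

  # type-II analysis of deviance: each term dropped from the appropriate
  # nested model (interactions against the full model)
  base_terms <- covariates[!grepl(":", covariates)]
  inter_terms <- setdiff(covariates, base_terms)
  refit <- function(terms) {
    if (!length(terms)) {
      null_fit <- survival::coxph(
        as.formula("survival::Surv(latency, !censored) ~ 1"),
        data = tbl, ties = ties
      )
      return(null_fit)
    }
    survival::coxph(
      as.formula(paste(
        "survival::Surv(latency, !censored) ~",
        paste(terms, collapse = " + ")
      )),
      data = tbl, ties = ties
    )
  }
  loglik <- function(f) f$loglik[length(f$loglik)]
  ndf <- function(f) sum(!is.na(f$coefficients))
  main_fit <- refit(base_terms)
  tests <- dplyr::bind_rows(c(
    lapply(base_terms, function(tm) {
      red <- refit(setdiff(base_terms, tm))
      chisq <- max(2 * (loglik(main_fit) - loglik(red)), 0)
      df <- ndf(main_fit) - ndf(red)
      tibble::tibble(term = tm, chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
    }),
    lapply(inter_terms, function(tm) {
      red <- refit(setdiff(covariates, tm))
      chisq <- max(2 * (loglik(fit) - loglik(red)), 0)
      df <- ndf(fit) - ndf(red)
      tibble::tibble(term = tm, chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
    })
  ))
  structure(
    list(fit = fit, coefficients = coefs, tests = tests, ties = ties),
    class = "protoy_cox"
  )
}

#' @export
print.protoy_cox <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), ",
    x$fit$n, " records, ", x$fit$nevent, " events\n",
    sep = ""
  )
  print(x$coefficients)
  cat("Analysis of deviance (type II):\n")
  print(x$tests)
  invisible(x)
}

#' Likelihood-ratio comparison of nested models
#'
#' `chisq = 2 (loglik_full - loglik_reduced)` with degrees of freedom equal
#' to the difference in parameter count and an upper-tail p-value. Works
#' for any pair of fits with `logLik()` methods on the same data (`lm`
#' fits should use maximum likelihood, which `logLik.lm` reports).
#'
#' @param full,reduced Nested fitted models (the reduced model's terms must
#'   be a subset of the full model's).
#' @return Tibble with columns `chisq`, `df`, `p`.
#' @export
compare_nested_models <- function(full, reduced) {
  term_labels <- function(m) attr(stats::terms(m), "term.labels")
  tf <- tryCatch(term_labels(full), error = function(e) NULL)
  tr <- tryCatch(term_labels(reduced), error = function(e) NULL)
  if (!is.null(tf) && !is.null(tr) && !all(tr %in% tf)) {
    abort("Models are not nested: reduced model has terms absent from the full model.")
  }
  ll_f <- logLik(full)
  ll_r <- logLik(reduced)
  n_f <- attr(ll_f, "nobs") %||% NA
  n_r <- attr(ll_r, "nobs") %||% NA
  if (!is.na(n_f) && !is.na(n_r) && n_f != n_r) {
    abort("Models were fit to different numbers of observations.")
  }
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0) abort("The full model has fewer parameters than the reduced model.")
  chisq <- max(2 * (as.numeric(ll_f) - as.numeric(ll_r)), 0)
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  tibble::tibble(chisq = chisq, df = df, p = p)
}
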