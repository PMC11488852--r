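#' Resampling null for the mean log2 fold-change of a gene set
#'
#' Compares the observed mean log2 fold-change of a gene set against the
#' distribution of means of `n_subsets` random subsets of the same size
#' drawn without replacement from the background fold-change values. The
#' p-value is the proportion of subsets whose mean is strictly more extreme
#' than the observed mean in the stated tail (lower: more negative; upper:
#' more positive). With `plus_one = TRUE` the small-sample correction
#' `(b + 1) / (n + 1)` is applied instead.
#'
#' @param observed_ids Character vector of gene IDs in the observed set.
#' @param all_fc Named numeric vector mapping gene IDs to log2 fold-changes
#'   (or a data frame with columns `gene`, `log2fc`).
#' @param n_subsets Number of random subsets (default 10,000).
#' @param tail `"lower"` or `"upper"`.
#' @param seed Integer seed (recorded in the output).
#' @param plus_one Apply the `+1` correction.
#'
#' @return Tibble with columns `observed_mean`, `p`, `n_subsets`, `n_set`,
#'   `tail`, `seed`.
#' @export
resample_fold_change_null <- function(observed_ids, all_fc, n_subsets = 10000,
                                      tail = c("lower", "upper"), seed = 1L,
                                      plus_one = FALSE) {
  tail <- match.arg(tail)
  if (!length(observed_ids)) abort("Observed gene set is empty.")
  if (is.data.frame(all_fc)) all_fc <- setNames(all_fc$log2fc, all_fc$gene)
  missing <- setdiff(observed_ids, names(all_fc))
  if (length(missing)) {
    abort(paste0("Observed gene(s) absent from the background: ", paste(missing, collapse = ", ")))
  }
  k <- length(observed_ids)
  if (k > length(all_fc)) abort("Observed set larger than the background.")
  obs <- mean(all_fc[observed_ids])
  values <- unname(all_fc)

  set.seed(seed)
  null_means <- vapply(
    seq_len(n_subsets),
    function(i) mean(values[sample.int(length(values), k)]),
    numeric(1)
  )
  extreme <- if (tail == "lower") sum(null_means < obs) else sum(null_means > obs)
  p <- if (plus_one) (extreme + 1) / (n_subsets + 1) else extreme / n_subsets
  tibble::tibble(
    observed_mean = obs, p = p, n_subsets = n_subsets,
    n_set = k, tail = tail, seed = as.integer(seed)
  )
}

#' Direction-specific ortholog resampling test
#'
#' Tests whether house fly orthologs of genes up- (or down-) regulated upon
#' Obp56h knockdown in D. melanogaster have more extreme mean log2
#' fold-changes between Y^M and III^M males than random gene sets: the
#' up-regulated set is tested in the upper tail, the down-regulated set in
#' the lower tail. Subset sizes come from the ortholog table itself.
#'
#' @param orthologs Data frame with columns `mdom_id` (house fly gene ID)
#'   and `direction` (`"up"` or `"down"` in the knockdown experiment).
#' @param all_fc Named fold-change vector or data frame (see
#'   [resample_fold_change_null()]).
#' @param direction `"up"` or `"down"`.
#' @param n_subsets,seed,plus_one Passed through.
#' @return Tibble as in [resample_fold_change_null()], plus `direction`.
#' @export
ortholog_direction_test <- function(orthologs, all_fc, direction = c("up", "down"),
                                    n_subsets = 10000, seed = 1L, plus_one = FALSE) {
  direction <- match.arg(direction)
  tbl <- tibble::as_tibble(orthologs)
  stopifnot(all(c("mdom_id", "direction") %in% names(tbl)))
  if (!all(tbl$direction %in% c("up", "down"))) {
    abort("`direction` column must contain only 'up' and 'down'.")
  }
  ids <- tbl$mdom_id[tbl$direction == direction]
  if (!length(ids)) abort(sprintf("No orthologs in the '%s' direction.", direction))
  out <- resample_fold_change_null(
    ids, all_fc,
    n_subsets = n_subsets,
    tail = if (direction == "up") "upper" else "lower",
    seed = seed, plus_one = plus_one
  )
  dplyr::mutate(out, direction = direction)
}

#' Normalize heterogeneous tissue expression tables
#'
#' Expression values from different platforms (microarray intensity, RPKM,
#' TPM) are made comparable within a tissue sample by dividing each value
#' by the mean over the included genes of that tissue. Rows are excluded
#' (flagged, with a reason, normalized value `NA`) when the raw value is 0,
#' when fewer than `min_replicates` replicates detected the gene (if an
#' `n_replicates` column is present), or when a `status` column is present
#' and not `"OK"`. When a `gene` column accompanies transcript-level rows,
#' transcript values are first averaged per gene within each tissue.
#'
#' @param table Data frame with columns `id`, `tissue`, `value`, and
#'   optionally `gene`, `n_replicates`, `status`.
#' @param min_replicates Minimum replicate count for microarray rows.
#' @return Tibble with columns `id`, `tissue`, `value`, `excluded`,
#'   `reason`, `normalized`.
#' @export
normalize_tissue_expression <- function(table, min_replicates = 4) {
  tbl <- tibble::as_tibble(table)
  stopifnot(all(c("id", "tissue", "value") %in% names(tbl)))
  if ("gene" %in% names(tbl)) {
    tbl <- tbl |>
      dplyr::group_by(.data$gene, .data$tissue) |>
      dplyr::summarise(
        id = .data$gene[1],
        value = mean(.data$value),
        n_replicates = if ("n_replicates" %in% names(tbl)) min(.data$n_replicates) else NA_real_,
        status = if ("status" %in% names(tbl)) {
          if (all(.data$status == "OK")) "OK" else "not_OK"
        } else {
          NA_character_
        },
        .groups = "drop"
      ) |>
      dplyr::select(-"gene")
  }
  if (!"n_replicates" %in% names(tbl)) tbl$n_replicates <- NA_real_
  if (!"status" %in% names(tbl)) tbl$status <- NA_character_

  tbl <- tbl |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$value == 0 ~ "zero_value",
        !is.na(.data$n_replicates) & .data$n_replicates < min_replicates ~ "too_few_replicates",
        !is.na(.data$status) & .data$status != "OK" ~ "failed_threshold",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$reason)
    )
  means <- tbl |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(tissue_mean = mean(.data$value), .groups = "drop")
  empty <- setdiff(unique(tbl$tissue), means$tissue)
  if (length(empty)) {
    abort(paste0("Tissue(s) with no included genes: ", paste(empty, collapse = ", ")))
  }
  tbl |>
    dplyr::left_join(means, by = "tissue") |>
    dplyr::mutate(normalized = ifelse(.data$excluded, NA_real_, .data$value / .data$tissue_mean)) |>
    dplyr::select("id", "tissue", "value", "excluded", "reason", "normalized")
}
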