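#' Test-retest Pearson correlations per taste quality and method
#'
#' Standard Pearson r between test and retest threshold estimates, computed
#' separately within each grouping cell. Cells with zero variance in either
#' margin have no defined correlation and are reported as `NA` with a note.
#'
#' @param pairs A pair table from [threshold_pairs()] (columns `quality`,
#'   `method`, `test`, `retest`), or any data frame with those columns.
#' @param by Grouping columns.
#' @return A tibble with one row per cell: grouping columns, `n`, `r`,
#'   `note`.
#' @export
test_retest_corr <- function(pairs, by = c("quality", "method")) {
  stopifnot(all(c("test", "retest") %in% names(pairs)))
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() < 3 || sd(.data$test) == 0 || sd(.data$retest) == 0)
        NA_real_ else cor(.data$test, .data$retest),
      note = dplyr::case_when(
        dplyr::n() < 3 ~ "fewer than 3 pairs",
        sd(.data$test) == 0 || sd(.data$retest) == 0 ~
          "zero variance in a margin",
        TRUE ~ NA_character_
      ),
      .groups = "drop"
    )
}

#' Per-cell summary of test, retest and their difference
#'
#' Arithmetic means and standard deviations (log10 mM) of the test estimates,
#' the retest estimates, and the per-pair difference test minus retest.
#'
#' @inheritParams test_retest_corr
#' @return A tibble with columns `n`, `test_mean`, `test_sd`, `retest_mean`,
#'   `retest_sd`, `diff_mean`, `diff_sd` per cell.
#' @export
summarize_pairs <- function(pairs, by = c("quality", "method")) {
  stopifnot(all(c("test", "retest") %in% names(pairs)))
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      test_mean = mean(.data$test), test_sd = sd(.data$test),
      retest_mean = mean(.data$retest), retest_sd = sd(.data$retest),
      diff_mean = mean(.data$test - .data$retest),
      diff_sd = sd(.data$test - .data$retest),
      .groups = "drop"
    )
}

#' Histogram of threshold estimates over the dilution steps
#'
#' Assigns every estimate to its nearest prepared dilution step (log10
#' distance, ties toward the stronger concentration, as in [nearest_step()])
#' and counts per step. Estimates in the two "extreme" bins — the strongest
#' and the weakest prepared concentration — indicate an insufficient
#' concentration range.
#'
#' @param estimates Threshold estimates in log10 mM.
#' @param series The [dilution_series()] the estimates belong to.
#' @return A tibble with `sample`, `conc_mM`, `log10_mM`, `count`,
#'   `extreme`; the total count equals `length(estimates)` and the number of
#'   estimates in extreme bins is attached as attribute `n_extreme`.
#' @export
histogram_by_step <- function(estimates, series) {
  stopifnot(inherits(series, "dilution_series"))
  estimates <- estimates[!is.na(estimates)]
  idx <- if (length(estimates)) nearest_step(series, estimates) else integer()
  counts <- tabulate(idx, nbins = series$n_steps)
  out <- tibble::tibble(
    sample = seq_len(series$n_steps),
    conc_mM = series$concentrations,
    log10_mM = series$log10_conc,
    count = counts,
    extreme = seq_len(series$n_steps) %in% c(1L, series$n_steps)
  )
  attr(out, "n_extreme") <- sum(counts[c(1L, series$n_steps)])
  out
}
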