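#' Run one threshold-estimation session with either method
#'
#' Thin dispatcher over [run_siam_session()] and [run_quest_session()].
#'
#' @param method `"SIAM"` or `"QUEST"`.
#' @inheritParams run_siam_session
#' @param ... Further arguments passed to the method's driver.
#' @return A `taste_session` object.
#' @export
run_session <- function(method = c("SIAM", "QUEST"), series, respond, ...) {
  method <- match.arg(method)
  if (method == "SIAM") run_siam_session(series, respond, ...)
  else run_quest_session(series, respond, ...)
}

#' @export
print.taste_session <- function(x, ...) {
  cat(sprintf("%s session: %d trials", x$method, x$n_trials))
  if (!is.na(x$participant)) cat(sprintf(" (participant %s)", x$participant))
  cat("\n")
  if (is.na(x$exclusion)) {
    cat(sprintf("  threshold estimate: %.4f log10 mM (%.4g mM)\n",
                x$estimate, 10 ^ x$estimate))
  } else {
    cat(sprintf("  excluded: %s\n", x$exclusion))
  }
  invisible(x)
}

quality_levels <- c("sweet", "sour", "salty", "bitter")

#' Plan a full test-retest study design
#'
#' Builds the complete crossing of participants x 4 taste qualities x
#' 2 methods x 2 sessions (test, retest). Methods are never interleaved: a
#' participant completes test and retest with one method in consecutive
#' visits before switching to the other. Method order alternates across
#' participants and taste-quality orders are counterbalanced by cycling a
#' 4 x 4 Latin square; within a participant the quality order is identical in
#' test and retest.
#'
#' @param n_participants Number of participants (>= 1).
#' @return A tibble with one planned estimation per row: `participant`,
#'   `visit`, `method`, `session`, `quality_position`, `quality`.
#' @examples
#' nrow(build_design(42))  # 672
#' @export
build_design <- function(n_participants) {
  stopifnot(n_participants >= 1)
  # cyclic Latin square over the four qualities
  latin <- t(vapply(0:3, function(r) quality_levels[(0:3 + r) %% 4 + 1],
                    character(4)))
  purrr::map_dfr(seq_len(n_participants), function(p) {
    qualities <- latin[(p - 1) %% 4 + 1, ]
    methods <- if (p %% 2 == 1) c("SIAM", "QUEST") else c("QUEST", "SIAM")
    tidyr::expand_grid(
      block = 1:2, session = c("test", "retest"), quality_position = 1:4
    ) |>
      dplyr::mutate(
        participant = p,
        method = methods[.data$block],
        visit = (.data$block - 1) * 2 + ifelse(.data$session == "test", 1, 2),
        quality = qualities[.data$quality_position]
      ) |>
      dplyr::select("participant", "visit", "method", "session",
                    "quality_position", "quality")
  }) |>
    dplyr::arrange(.data$participant, .data$visit, .data$quality_position)
}

#' Simulate a full cohort of threshold estimations
#'
#' Runs every planned estimation of a [build_design()] plan against simulated
#' observers. Each participant x quality cell gets one observer whose true
#' threshold is drawn from a normal distribution centred on the middle of
#' that quality's dilution range (log10 scale); the same observer responds in
#' test and retest of both methods, so test-retest structure is real.
#'
#' @param design A design tibble from [build_design()], or an integer number
#'   of participants.
#' @param series_list Named list of [dilution_series()], one per quality;
#'   defaults to the four packaged series.
#' @param threshold_sd Between-participant SD of true thresholds in log10
#'   units.
#' @param false_alarm_rate Blank false-alarm probability of every observer.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param ... Passed on to the session drivers.
#' @return A list with `sessions` (list of `taste_session` objects),
#'   `thresholds` (the cohort threshold table: participant, quality, method,
#'   session, estimate, exclusion) and `observers` (true parameters).
#' @export
simulate_cohort <- function(design, series_list = NULL, threshold_sd = 0.6,
                            false_alarm_rate = 0.15, seed = 1L, ...) {
  if (is.numeric(design) && length(design) == 1) {
    design <- build_design(design)
  }
  if (is.null(series_list)) {
    series_list <- purrr::set_names(purrr::map(quality_levels, taste_series),
                                    quality_levels)
  }
  withr::with_seed(seed, {
    obs_tab <- design |>
      dplyr::distinct(.data$participant, .data$quality) |>
      dplyr::mutate(
        true_threshold = purrr::map_dbl(.data$quality, function(q) {
          s <- series_list[[q]]
          centre <- mean(range(s$log10_conc))
          stats::rnorm(1, centre, threshold_sd)
        }),
        false_alarm_rate = false_alarm_rate
      )
    sessions <- purrr::pmap(design, function(participant, visit, method,
                                             session, quality_position,
                                             quality) {
      ob <- obs_tab[obs_tab$participant == participant &
                      obs_tab$quality == quality, ]
      observer <- simulated_observer(
        weibull_pf(ob$true_threshold),
        false_alarm_rate = ob$false_alarm_rate
      )
      run_session(method, series_list[[quality]], observer,
                  participant = as.character(participant),
                  session_label = session, ...)
    })
    thresholds <- dplyr::bind_cols(
      design,
      purrr::map_dfr(sessions, function(s) {
        tibble::tibble(estimate = s$estimate, exclusion = s$exclusion,
                       n_trials = s$n_trials)
      })
    )
    list(sessions = sessions, thresholds = thresholds, observers = obs_tab)
  })
}

#' Keep thresholds only in complete test-retest pairs
#'
#' If either the test or the retest threshold of a participant x quality x
#' method cell is missing (excluded), the other member of the pair is removed
#' as well. Removal counts per method are attached as the `"removed"`
#' attribute.
#'
#' @param thresholds Cohort threshold table with columns `participant`,
#'   `quality`, `method`, `session`, `estimate` (NA when excluded).
#' @return The retained rows, with attribute `removed` (named integer vector
#'   per method: number of rows dropped).
#' @export
preprocess_pairs <- function(thresholds) {
  stopifnot(all(c("participant", "quality", "method", "session",
                  "estimate") %in% names(thresholds)))
  marked <- thresholds |>
    dplyr::group_by(.data$participant, .data$quality, .data$method) |>
    dplyr::mutate(pair_complete = sum(!is.na(.data$estimate) &
                                        .data$session %in%
                                          c("test", "retest")) == 2) |>
    dplyr::ungroup()
  kept <- marked |>
    dplyr::filter(.data$pair_complete) |>
    dplyr::select(-"pair_complete")
  removed <- marked |>
    dplyr::filter(!.data$pair_complete) |>
    dplyr::count(.data$method)
  rem <- purrr::set_names(removed$n, removed$method)
  attr(kept, "removed") <- rem
  kept
}

#' Pivot a retained threshold table to one row per test-retest pair
#'
#' @param retained Output of [preprocess_pairs()] (long format).
#' @return A tibble with columns `participant`, `quality`, `method`, `test`,
#'   `retest` (estimates in log10 mM).
#' @export
threshold_pairs <- function(retained) {
  retained |>
    dplyr::select("participant", "quality", "method", "session",
                  "estimate") |>
    tidyr::pivot_wider(names_from = "session", values_from = "estimate") |>
    dplyr::filter(!is.na(.data$test), !is.na(.data$retest))
}

#' Write / read a session log as delimited text
#'
#' One session per file: commented `#meta key<TAB>value` header lines (method,
#' identifiers, estimate, exclusion, seed, the dilution series) followed by
#' the tab-separated trial table. `read_session()` reconstructs a
#' `taste_session` with the same trials, series, estimate and exclusion.
#'
#' @param session A `taste_session`.
#' @param path File path.
#' @return `write_session()` returns `session` invisibly; `read_session()`
#'   a `taste_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "taste_session"))
  s <- session$series
  meta <- c(
    method = session$method,
    participant = as.character(session$participant),
    session_label = as.character(session$session_label),
    seed = as.character(session$seed %||% NA),
    estimate = formatC(session$estimate, digits = 15, format = "g"),
    exclusion = as.character(session$exclusion),
    tastant = s$tastant,
    quality = as.character(s$quality),
    start_index = as.character(s$start_index),
    concentrations = paste(formatC(s$concentrations, digits = 15,
                                   format = "g"), collapse = ",")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#meta %s\t%s", names(meta), meta), con)
  trials <- session$trials
  writeLines(paste(names(trials), collapse = "\t"), con)
  utils::write.table(trials, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(session)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#meta ", lines, value = TRUE)
  kv <- sub("^#meta ", "", meta_lines)
  keys <- sub("\t.*$", "", kv)
  vals <- sub("^[^\t]*\t", "", kv)
  meta <- purrr::set_names(vals, keys)
  body <- lines[!grepl("^#meta ", lines)]
  trials <- utils::read.delim(text = paste(body, collapse = "\n")) |>
    tibble::as_tibble()
  series <- dilution_series(
    as.numeric(strsplit(meta[["concentrations"]], ",")[[1]]),
    tastant = meta[["tastant"]],
    start_index = as.integer(meta[["start_index"]]),
    quality = meta[["quality"]], check_spacing = FALSE
  )
  cls <- if (meta[["method"]] == "SIAM") "siam_session" else "quest_session"
  structure(
    list(method = meta[["method"]], series = series, trials = trials,
         n_trials = nrow(trials),
         seed = if (meta[["seed"]] == "NA") NULL else
           as.integer(meta[["seed"]]),
         participant = meta[["participant"]],
         session_label = meta[["session_label"]],
         estimate = if (meta[["estimate"]] == "NA") NA_real_ else
           as.numeric(meta[["estimate"]]),
         exclusion = if (meta[["exclusion"]] == "NA") NA_character_ else
           meta[["exclusion"]],
         config = list(), erratic = FALSE),
    class = c(cls, "taste_session")
  )
}
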