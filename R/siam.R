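#' Single-interval adjustment matrix
#'
#' The signed level adjustments applied after each trial outcome, in the
#' strength convention: positive steps move toward a STRONGER concentration,
#' negative steps toward a weaker one. The default matrix tracks a target
#' performance of t = 0.5 (hit rate minus false-alarm rate), i.e. a 75%
#' Yes-proportion operating point: hit -1, miss +1, false alarm +2, correct
#' rejection 0. During the initial boost phase — until the first miss or
#' false alarm — hits move 3 steps weaker instead of 1, to advance to the
#' threshold region quickly.
#'
#' @param hit Step after a hit (target/Yes); must be negative.
#' @param miss Step after a miss (target/No); must be positive.
#' @param false_alarm Step after a false alarm (blank/Yes); must be positive.
#' @param correct_rejection Step after a correct rejection (blank/No);
#'   must be non-negative.
#' @param hit_boost Step after a hit while the boost phase is active.
#' @return An object of class `adjustment_matrix`.
#' @export
adjustment_matrix <- function(hit = -1, miss = 1, false_alarm = 2,
                              correct_rejection = 0, hit_boost = -3) {
  if (!(hit < 0 && miss > 0 && false_alarm > 0 && correct_rejection >= 0)) {
    stop("require hit < 0, miss > 0, false_alarm > 0, correct_rejection >= 0",
         call. = FALSE)
  }
  structure(
    list(hit = hit, miss = miss, false_alarm = false_alarm,
         correct_rejection = correct_rejection, hit_boost = hit_boost),
    class = "adjustment_matrix"
  )
}

#' @export
print.adjustment_matrix <- function(x, ...) {
  cat("Adjustment matrix (positive = stronger):\n")
  cat(sprintf("  hit %+d (boost %+d), miss %+d, false alarm %+d, correct rejection %+d\n",
              x$hit, x$hit_boost, x$miss, x$false_alarm, x$correct_rejection))
  invisible(x)
}

#' Classify a yes-no response against the stimulus kind
#'
#' The 2x2 signal-detection outcome: target/Yes = hit, target/No = miss,
#' blank/Yes = false alarm, blank/No = correct rejection.
#'
#' @param kind `"target"` or `"blank"` (vectorised).
#' @param response `"yes"` or `"no"` (vectorised).
#' @return Character vector of outcome classes.
#' @export
classify_response <- function(kind, response) {
  stopifnot(all(kind %in% c("target", "blank")),
            all(response %in% c("yes", "no")))
  dplyr::case_when(
    kind == "target" & response == "yes" ~ "hit",
    kind == "target" & response == "no" ~ "miss",
    kind == "blank" & response == "yes" ~ "false_alarm",
    TRUE ~ "correct_rejection"
  )
}

#' Schedule targets and blanks for a staircase session
#'
#' Draws a random arrangement of a fixed multiset of `floor(n_trials / 2)`
#' blanks and the remaining targets (exactly 50% blanks for even budgets)
#' in which no more than `max_blank_run` blanks occur in succession. Uses
#' the current R random stream.
#'
#' The draw is uniform over all arrangements of the fixed blank/target
#' multiset that satisfy the run constraint: completions are counted by
#' dynamic programming and each trial's stimulus is sampled with probability
#' proportional to the number of valid completions it leaves. Count tables
#' are cached per (blanks, targets, run-limit) within the session.
#'
#' @param n_trials Total number of trials.
#' @param max_blank_run Longest permitted run of consecutive blanks.
#' @return Character vector of `"target"` / `"blank"` of length `n_trials`.
#' @export
schedule_stimuli <- function(n_trials, max_blank_run = 2) {
  stopifnot(n_trials >= 2, max_blank_run >= 1)
  n_blanks <- n_trials %/% 2
  n_targets <- n_trials - n_blanks
  counts <- schedule_counts(n_blanks, n_targets, max_blank_run)
  b <- n_blanks; t <- n_targets; r <- 0L
  out <- character(n_trials)
  for (i in seq_len(n_trials)) {
    c_blank <- if (b > 0 && r < max_blank_run) counts[b, t + 1L, r + 2L] else 0
    c_target <- if (t > 0) counts[b + 1L, t, 1L] else 0
    if (c_blank + c_target == 0) {
      stop("no valid schedule exists for these counts", call. = FALSE)
    }
    if (runif(1) < c_blank / (c_blank + c_target)) {
      out[i] <- "blank"; b <- b - 1L; r <- r + 1L
    } else {
      out[i] <- "target"; t <- t - 1L; r <- 0L
    }
  }
  out
}

# number of arrangements of b blanks and t targets whose every blank run is
# <= max_run, given a trailing run of r blanks; dims [b+1, t+1, r+1]
schedule_counts <- local({
  cache <- new.env(parent = emptyenv())
  function(n_blanks, n_targets, max_run) {
    key <- paste(n_blanks, n_targets, max_run, sep = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    a <- array(0, dim = c(n_blanks + 1L, n_targets + 1L, max_run + 1L))
    a[1L, , ] <- 1  # no blanks left: any all-target completion is valid
    for (b in seq_len(n_blanks)) {
      for (t in 0:n_targets) {
        for (r in 0:max_run) {
          via_blank <- if (r < max_run) a[b, t + 1L, r + 2L] else 0
          via_target <- if (t > 0) a[b + 1L, t, 1L] else 0
          a[b + 1L, t + 1L, r + 1L] <- via_blank + via_target
        }
      }
    }
    cache[[key]] <- a
    a
  }
})

outcome_step <- function(outcome, matrix, boost_active) {
  switch(outcome,
         hit = if (boost_active) matrix$hit_boost else matrix$hit,
         miss = matrix$miss,
         false_alarm = matrix$false_alarm,
         correct_rejection = matrix$correct_rejection)
}

#' Run one SIAM staircase session
#'
#' Drives a complete modified-SIAM threshold estimation: a seeded schedule
#' with 50% blanks (no run of three blanks), level updates from the
#' adjustment matrix with the boost phase active until the first miss or
#' false alarm, clamping at the ends of the prepared series, and reversal-
#' mean threshold extraction with the exclusion rules of
#' [siam_threshold()].
#'
#' @param series A [dilution_series()].
#' @param respond A [simulated_observer()], or a function
#'   `function(kind, conc_mM, log10_mM)` returning `"yes"`/`"no"` (e.g. an
#'   interactive prompt).
#' @param matrix An [adjustment_matrix()].
#' @param n_trials Trial budget (the procedure always runs the full budget).
#' @param boost Whether the initial boost phase is enabled.
#' @param start_index Starting level; defaults to the series' marked start.
#' @param seed Optional integer seed; equal seeds give byte-identical
#'   sessions for the same observer.
#' @param participant,session_label Optional identifiers carried into the
#'   record.
#' @return An object of class `siam_session` (and `taste_session`), with the
#'   trial-by-trial log as a tibble (`tidy()`), the estimate or exclusion
#'   (`glance()`), and the final tracked level.
#' @export
run_siam_session <- function(series, respond, matrix = adjustment_matrix(),
                             n_trials = 30, boost = TRUE,
                             start_index = series$start_index, seed = NULL,
                             participant = NA_character_,
                             session_label = NA_character_) {
  stopifnot(inherits(series, "dilution_series"),
            inherits(matrix, "adjustment_matrix"), n_trials >= 2)
  respond_fun <- as_respond_fun(respond)
  runner <- function() {
    sched <- schedule_stimuli(n_trials)
    level <- as.integer(start_index)
    boost_active <- boost
    n <- series$n_steps
    levels <- integer(n_trials)
    responses <- character(n_trials)
    outcomes <- character(n_trials)
    steps <- integer(n_trials)
    boosts <- logical(n_trials)
    clampeds <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      kind <- sched[i]
      lg <- series$log10_conc[level]
      target <- kind == "target"
      response <- respond_fun(kind, if (target) series$concentrations[level]
                                    else 0,
                              if (target) lg else -Inf)
      outcome <- if (target) {
        if (response == "yes") "hit" else "miss"
      } else {
        if (response == "yes") "false_alarm" else "correct_rejection"
      }
      step <- outcome_step(outcome, matrix, boost_active)
      raw <- level - step  # stronger = lower index
      levels[i] <- level
      responses[i] <- response
      outcomes[i] <- outcome
      steps[i] <- as.integer(step)
      boosts[i] <- boost_active
      clampeds[i] <- raw < 1L || raw > n
      if (boost_active && outcome %in% c("miss", "false_alarm")) {
        boost_active <- FALSE
      }
      level <- max(1L, min(n, as.integer(raw)))
    }
    is_target <- sched == "target"
    tibble::tibble(
      trial = seq_len(n_trials), kind = sched, level = levels,
      conc_mM = ifelse(is_target, series$concentrations[levels], NA_real_),
      log10_mM = ifelse(is_target, series$log10_conc[levels], NA_real_),
      level_log10 = series$log10_conc[levels], response = responses,
      outcome = outcomes, step = steps, boost = boosts, clamped = clampeds
    )
  }
  trials <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  out <- structure(
    list(method = "SIAM", series = series, trials = trials,
         n_trials = n_trials, seed = seed, participant = participant,
         session_label = session_label,
         final_level = final_level(trials, series),
         config = list(matrix = matrix, boost = boost,
                       start_index = start_index),
         erratic = FALSE, estimate = NA_real_, exclusion = NA_character_),
    class = c("siam_session", "taste_session")
  )
  est <- siam_threshold(out)
  out$estimate <- est$estimate
  out$exclusion <- est$exclusion
  out
}

final_level <- function(trials, series) {
  last <- trials[nrow(trials), ]
  raw <- last$level - last$step
  max(1L, min(series$n_steps, as.integer(raw)))
}

as_respond_fun <- function(respond) {
  if (inherits(respond, "sim_observer")) {
    function(kind, conc_mM, log10_mM) {
      observer_respond(respond, kind, if (kind == "target") log10_mM else NULL)
    }
  } else if (is.function(respond)) {
    respond
  } else {
    stop("respond must be a sim_observer or a function", call. = FALSE)
  }
}

#' Detect staircase reversals in a trial log
#'
#' A reversal is a trial whose applied non-zero step has the opposite sign to
#' the previous applied non-zero step; zero steps (correct rejections) are
#' skipped. The recorded reversal concentration is the tracked level
#' concentration at the reversal trial, in log10 mM.
#'
#' @param trials A trial-log tibble with columns `step` and `level_log10`
#'   (as produced by [run_siam_session()]), or a `siam_session`.
#' @return A tibble with columns `trial` and `log10_mM`, one row per
#'   reversal.
#' @export
detect_reversals <- function(trials) {
  if (inherits(trials, "siam_session")) trials <- trials$trials
  nz <- trials[trials$step != 0, , drop = FALSE]
  if (nrow(nz) < 2) {
    return(tibble::tibble(trial = integer(), log10_mM = numeric()))
  }
  flip <- sign(nz$step[-1]) != sign(nz$step[-nrow(nz)])
  rev <- nz[c(FALSE, flip), , drop = FALSE]
  tibble::tibble(trial = rev$trial, log10_mM = rev$level_log10)
}

#' Reversal-mean threshold from a set of reversal concentrations
#'
#' Removes the first reversal if the number of reversals is odd, or the first
#' two if it is even, then averages the remaining reversal concentrations in
#' log10 mM. Fewer than two retained reversals yield no estimate.
#'
#' @param values Reversal concentrations in log10 mM, in trial order.
#' @param min_retained Minimum number of retained reversals for a valid
#'   estimate.
#' @return A list with `estimate` (log10 mM or `NA`), `retained` (the values
#'   averaged) and `excluded` (logical).
#' @export
reversal_threshold <- function(values, min_retained = 2) {
  n <- length(values)
  drop <- if (n == 0) 0L else if (n %% 2 == 1) 1L else 2L
  retained <- if (n > drop) values[-seq_len(drop)] else numeric()
  if (length(retained) < min_retained) {
    list(estimate = NA_real_, retained = retained, excluded = TRUE)
  } else {
    list(estimate = mean(retained), retained = retained, excluded = FALSE)
  }
}

#' Threshold estimate and exclusion status for a SIAM session
#'
#' Applies, in order, the session-level exclusion rules — erratic responses
#' (a manual flag, see [mark_erratic()]), a Yes response to the weakest
#' prepared concentration, a No response to the strongest (both meaning the
#' staircase demanded a level beyond the prepared range), no miss observed —
#' and then the reversal-mean rule of [reversal_threshold()].
#'
#' @param session A `siam_session`.
#' @return A list with `estimate` (log10 mM or `NA`), `exclusion` (reason
#'   code or `NA`), and the `reversals` tibble.
#' @export
siam_threshold <- function(session) {
  stopifnot(inherits(session, "siam_session"))
  trials <- session$trials
  n <- session$series$n_steps
  revs <- detect_reversals(trials)
  targets <- trials[trials$kind == "target", , drop = FALSE]
  exclusion <- NA_character_
  if (isTRUE(session$erratic)) {
    exclusion <- "erratic_responses"
  } else if (any(targets$level == n & targets$response == "yes")) {
    exclusion <- "yes_at_lowest"
  } else if (any(targets$level == 1 & targets$response == "no")) {
    exclusion <- "no_at_highest"
  } else if (!any(targets$outcome == "miss")) {
    exclusion <- "no_miss"
  }
  est <- reversal_threshold(revs$log10_mM)
  if (is.na(exclusion) && est$excluded) exclusion <- "too_few_reversals"
  list(estimate = if (is.na(exclusion)) est$estimate else NA_real_,
       exclusion = exclusion, reversals = revs)
}

#' Flag a session as showing erratic responses
#'
#' Erratic responding has no automated criterion; it is an experimenter
#' judgment recorded on the session. Flagging re-derives the estimate, which
#' becomes an exclusion.
#'
#' @param session A `siam_session`.
#' @param erratic Logical flag.
#' @return The updated session.
#' @export
mark_erratic <- function(session, erratic = TRUE) {
  stopifnot(inherits(session, "siam_session"))
  session$erratic <- isTRUE(erratic)
  est <- siam_threshold(session)
  session$estimate <- est$estimate
  session$exclusion <- est$exclusion
  session
}
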