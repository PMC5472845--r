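#' Tidy the trial-by-trial log of a session
#'
#' @param x A `taste_session`.
#' @param ... Unused.
#' @return The trial log as a tibble, one row per trial.
#' @method tidy taste_session
#' @export
tidy.taste_session <- function(x, ...) {
  x$trials
}

#' One-row summary of a session
#'
#' @param x A `taste_session`.
#' @param ... Unused.
#' @return A one-row tibble: participant, method, session label, number of
#'   trials, estimate (log10 mM), exclusion code, and for SIAM the reversal
#'   count.
#' @method glance taste_session
#' @export
glance.taste_session <- function(x, ...) {
  out <- tibble::tibble(
    participant = x$participant, method = x$method,
    session = x$session_label, n_trials = x$n_trials,
    estimate = x$estimate, exclusion = x$exclusion
  )
  if (inherits(x, "siam_session")) {
    out$n_reversals <- nrow(detect_reversals(x))
  }
  out
}

#' @rdname tidy.taste_session
#' @method tidy siam_operating_point
#' @export
tidy.siam_operating_point <- function(x, ...) x$runs

#' @rdname glance.taste_session
#' @method glance siam_operating_point
#' @export
glance.siam_operating_point <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x$runs), mean_hit_prob = x$mean_hit_prob,
    equilibrium = x$equilibrium,
    false_alarm_rate = x$config$false_alarm_rate,
    n_trials = x$config$n_trials
  )
}

#' @rdname tidy.taste_session
#' @method tidy quest_recovery
#' @export
tidy.quest_recovery <- function(x, ...) x$runs

#' @rdname glance.taste_session
#' @method glance quest_recovery
#' @export
glance.quest_recovery <- function(x, ...) x$summary
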