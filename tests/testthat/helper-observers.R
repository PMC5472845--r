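# Deterministic responder: Yes to any target at or above a fixed true
# threshold (log10 mM), No below it; never a false alarm on blanks.
oracle_responder <- function(true_threshold) {
  function(kind, conc_mM, log10_mM) {
    if (kind == "target" && log10_mM >= true_threshold) "yes" else "no"
  }
}

# Responder that replays a fixed sequence of responses, regardless of the
# stimulus. Errors if asked for more responses than scripted.
scripted_responder <- function(responses) {
  i <- 0
  function(kind, conc_mM, log10_mM) {
    i <<- i + 1
    if (i > length(responses)) stop("script exhausted")
    responses[i]
  }
}

# Minimal hand-built SIAM session record for unit-testing the threshold /
# exclusion logic in isolation from the runner.
fake_siam_session <- function(trials, series, erratic = FALSE) {
  structure(
    list(method = "SIAM", series = series, trials = trials,
         n_trials = nrow(trials), seed = NULL, participant = NA_character_,
         session_label = NA_character_, erratic = erratic,
         config = list(), estimate = NA_real_, exclusion = NA_character_),
    class = c("siam_session", "taste_session")
  )
}

# Trial-log row builder for fake sessions.
siam_trial_rows <- function(kind, level, response, step, series) {
  tibble::tibble(
    trial = seq_along(kind), kind = kind, level = level,
    conc_mM = ifelse(kind == "target", series$concentrations[level],
                     NA_real_),
    log10_mM = ifelse(kind == "target", series$log10_conc[level], NA_real_),
    level_log10 = series$log10_conc[level],
    response = response,
    outcome = classify_response(kind, response),
    step = step, boost = FALSE, clamped = FALSE
  )
}
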