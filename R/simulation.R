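#' Closed-form equilibrium hit probability of a SIAM staircase
#'
#' With 50% blanks, the expected level drift per trial is
#' \deqn{0.5\,[s_{miss}(1-p_h) + s_{hit} p_h] +
#'       0.5\,[s_{fa} p_{fa} + s_{cr}(1-p_{fa})]}
#' (strength convention, positive = stronger). Setting it to zero and solving
#' for the hit probability gives the staircase's operating point. For the
#' default matrix (hit -1, miss +1, false alarm +2, correct rejection 0) this
#' reduces to \eqn{p_h = 0.5 + p_{fa}}: an observer with a 25% false-alarm
#' rate is tracked at the 75% Yes point, i.e. target performance
#' t = p_h - p_fa = 0.5.
#'
#' @param matrix An [adjustment_matrix()].
#' @param p_fa The observer's constant blank false-alarm probability.
#' @return Equilibrium hit probability in (0, 1).
#' @export
equilibrium_oracle <- function(matrix, p_fa) {
  stopifnot(inherits(matrix, "adjustment_matrix"), p_fa >= 0, p_fa < 1)
  p_h <- (matrix$miss + matrix$false_alarm * p_fa +
            matrix$correct_rejection * (1 - p_fa)) /
    (matrix$miss - matrix$hit)
  if (!is.finite(p_h) || p_h <= 0 || p_h >= 1) {
    stop("no equilibrium hit probability in (0, 1) for this matrix",
         call. = FALSE)
  }
  p_h
}

#' Fine synthetic dilution grid for convergence studies
#'
#' A log-equidistant series much finer than any prepared tastant set
#' (default 61 steps of 0.05 log10 units), used to study the engines'
#' convergence properties separately from discretisation effects.
#'
#' @param center Centre of the grid in log10 mM.
#' @param half_span Half-width in log10 units.
#' @param step Step width in log10 units.
#' @return A [dilution_series()].
#' @export
fine_series <- function(center = 0, half_span = 1.5, step = 0.05) {
  n <- round(2 * half_span / step) + 1
  make_series(10 ^ (center + half_span), 10 ^ (center - half_span), n,
              tastant = "synthetic")
}

#' Monte-Carlo operating point of the SIAM staircase
#'
#' Simulates long staircases (post-boost matrix) against a seeded observer
#' with a Weibull hit function and a constant blank false-alarm rate, and
#' evaluates the observer's hit probability at each run's final tracked
#' level. At equilibrium the mean hit probability matches
#' [equilibrium_oracle()]: 75% Yes for the default matrix and a 25%
#' false-alarm rate.
#'
#' @param matrix An [adjustment_matrix()].
#' @param false_alarm_rate Observer blank false-alarm probability.
#' @param n_runs Number of simulated staircases.
#' @param n_trials Trials per staircase (long, to wash out the start).
#' @param observer_threshold True 80%-point of the observer's PF, log10 mM.
#' @param beta,guess,lapse Observer Weibull parameters.
#' @param series Dilution grid; defaults to a [fine_series()] centred on the
#'   observer threshold.
#' @param start_offset Starting level, log10 units above the observer
#'   threshold (clearly perceptible).
#' @param seed Integer seed.
#' @return An object of class `siam_operating_point`: per-run tibble
#'   (`runs`), `mean_hit_prob`, and the closed-form `equilibrium`.
#' @export
siam_operating_point <- function(matrix = adjustment_matrix(),
                                 false_alarm_rate = 0.25, n_runs = 500,
                                 n_trials = 200, observer_threshold = 0,
                                 beta = 3.5, guess = 0.01, lapse = 0.01,
                                 series = NULL, start_offset = 1,
                                 seed = 1L) {
  if (is.null(series)) series <- fine_series(center = observer_threshold)
  pf <- weibull_pf(observer_threshold, beta = beta, guess = guess,
                   lapse = lapse)
  observer <- simulated_observer(pf, false_alarm_rate = false_alarm_rate)
  start_index <- nearest_step(series, observer_threshold + start_offset)
  runs <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_runs), function(run) {
      s <- run_siam_session(series, observer, matrix = matrix,
                            n_trials = n_trials, boost = FALSE,
                            start_index = start_index)
      lg <- series$log10_conc[s$final_level]
      tibble::tibble(run = run, final_level = s$final_level,
                     final_log10 = lg, hit_prob = pf_eval(pf, lg))
    })
  })
  structure(
    list(runs = runs, mean_hit_prob = mean(runs$hit_prob),
         equilibrium = equilibrium_oracle(matrix, false_alarm_rate),
         config = list(matrix = matrix, false_alarm_rate = false_alarm_rate,
                       n_runs = n_runs, n_trials = n_trials,
                       observer_threshold = observer_threshold,
                       start_offset = start_offset, seed = seed)),
    class = "siam_operating_point"
  )
}

#' @export
print.siam_operating_point <- function(x, ...) {
  cat(sprintf(
    "SIAM operating point: mean hit probability %.3f over %d runs (equilibrium oracle %.3f)\n",
    x$mean_hit_prob, nrow(x$runs), x$equilibrium))
  invisible(x)
}

#' Monte-Carlo parameter recovery for the QUEST procedure
#'
#' Runs seeded QUEST sessions against matched simulated observers — observers
#' whose Yes probability follows the engine's assumed Weibull family with a
#' known threshold — and evaluates each observer's own psychometric function
#' at the session's posterior-mean estimate. For a well-calibrated procedure
#' the mean of these Yes-probabilities sits at the tracked target, 80%. True
#' thresholds are drawn uniformly from a small window around
#' `observer_threshold` so that results do not hinge on the alignment of a
#' single threshold with the stimulus grid.
#'
#' @param n_runs Number of simulated sessions.
#' @param observer_threshold Centre of the true-threshold window, log10 mM.
#' @param threshold_spread Width of the uniform true-threshold window,
#'   log10 units.
#' @param series Dilution grid; defaults to [fine_series()] centred on
#'   `observer_threshold`.
#' @param start_offset Starting level, log10 units above `observer_threshold`.
#' @param seed Integer seed.
#' @param ... Passed to [run_quest_session()] (placement mode, trial bounds,
#'   grain, prior SD, assumed PF parameters).
#' @return An object of class `quest_recovery`: per-run tibble `runs`
#'   (estimate, true threshold, trials used, Yes-probability at the
#'   estimate), and a one-row `summary` tibble with `mean_yes_prob`, `bias`,
#'   `rmse`, `mean_trials`.
#' @export
quest_recovery <- function(n_runs = 500, observer_threshold = 0,
                           threshold_spread = 0.5, series = NULL,
                           start_offset = 1, seed = 1L, ...) {
  if (is.null(series)) series <- fine_series(center = observer_threshold)
  runs <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_runs), function(run) {
      t_true <- observer_threshold +
        runif(1, -threshold_spread / 2, threshold_spread / 2)
      pf <- weibull_pf(t_true)
      observer <- simulated_observer(pf)
      start_index <- nearest_step(series, observer_threshold + start_offset)
      s <- run_quest_session(series, observer, start_index = start_index,
                             ...)
      est <- quest_threshold(s$state)
      tibble::tibble(run = run, true_threshold = t_true, estimate = est,
                     n_trials = s$n_trials,
                     yes_prob = pf_eval(pf, est),
                     excluded = !is.na(s$exclusion))
    })
  })
  summary <- tibble::tibble(
    n_runs = n_runs,
    mean_yes_prob = mean(runs$yes_prob),
    bias = mean(runs$estimate - runs$true_threshold),
    rmse = sqrt(mean((runs$estimate - runs$true_threshold) ^ 2)),
    mean_trials = mean(runs$n_trials)
  )
  structure(
    list(runs = runs, summary = summary,
         config = list(n_runs = n_runs,
                       observer_threshold = observer_threshold,
                       threshold_spread = threshold_spread,
                       start_offset = start_offset, seed = seed)),
    class = "quest_recovery"
  )
}

#' @export
print.quest_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "QUEST recovery over %d runs: mean Yes-probability at estimate %.3f, bias %+.4f log10 mM, RMSE %.4f, %.1f trials on average\n",
    s$n_runs, s$mean_yes_prob, s$bias, s$rmse, s$mean_trials))
  invisible(x)
}
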