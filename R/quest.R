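# Weibull Yes-probability at intensity x for a vector of candidate
# thresholds t (same asymptotes/slope for all; epsilon pre-computed)
psi_at <- function(x, t, beta, guess, lapse, epsilon) {
  guess + (1 - guess - lapse) * (1 - exp(-10 ^ (beta * (x - t + epsilon))))
}

#' Initialise a QUEST threshold grid and prior
#'
#' Builds the discrete threshold grid (log10 mM, uniform spacing `grain`)
#' covering `span` log10 units centred on the starting concentration, with a
#' Gaussian prior of standard deviation `prior_sd` centred there. With the
#' default `prior_sd = 20` (log10 units) the prior is effectively flat over
#' any realistic dilution range while remaining proper.
#'
#' @param start Starting intensity in log10 mM (prior centre).
#' @param prior_sd Prior standard deviation in log10 units.
#' @param grain Grid spacing in log10 units.
#' @param span Total grid span in log10 units.
#' @return A list with `t_values` and normalised `prior` masses.
#' @export
init_prior <- function(start, prior_sd = 20, grain = 0.01, span = 6) {
  stopifnot(is.finite(start), prior_sd > 0, grain > 0, span > 0)
  t_values <- seq(start - span / 2, start + span / 2, by = grain)
  prior <- dnorm(t_values, mean = start, sd = prior_sd)
  prior <- prior / sum(prior)
  list(t_values = t_values, prior = prior)
}

#' Initialise the state of a QUEST run
#'
#' The state carries the threshold grid, the accumulated log posterior
#' (log prior plus per-trial log likelihoods), the assumed Weibull
#' psychometric function (slope `beta`, asymptotes `guess` and `1 - lapse`,
#' threshold defined at `p_target` Yes), and the trial-count bounds.
#'
#' @inheritParams init_prior
#' @inheritParams weibull_pf
#' @param min_trials,max_trials Minimum / maximum number of trials.
#' @return An object of class `quest_state`.
#' @export
quest_init <- function(start, prior_sd = 20, grain = 0.01, span = 6,
                       beta = 3.5, guess = 0.01, lapse = 0.01,
                       p_target = 0.80, min_trials = 10, max_trials = 20) {
  grid <- init_prior(start, prior_sd, grain, span)
  structure(
    list(t_values = grid$t_values, log_post = log(grid$prior),
         n_trials = 0L, min_trials = as.integer(min_trials),
         max_trials = as.integer(max_trials),
         beta = beta, guess = guess, lapse = lapse, p_target = p_target,
         epsilon = epsilon_shift(beta, guess, lapse, p_target),
         start = start),
    class = "quest_state"
  )
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf(
    "QUEST state: %d trials, posterior mean %.4f log10 mM (grid %d points)\n",
    x$n_trials, quest_threshold(x), length(x$t_values)))
  invisible(x)
}

#' Bayesian update of the QUEST posterior after one trial
#'
#' Adds the log likelihood of the observed response to every grid point:
#' `log Psi(x; T = t)` for a Yes, `log(1 - Psi(x; T = t))` for a No. The
#' non-degenerate asymptotes (0.01 / 0.99) keep the posterior proper after
#' any response sequence. Updates commute, so response order at a fixed set
#' of intensities does not matter.
#'
#' @param state A `quest_state`.
#' @param x Presented intensity in log10 mM.
#' @param response `"yes"` or `"no"`.
#' @return The updated `quest_state`.
#' @export
update_posterior <- function(state, x, response) {
  stopifnot(inherits(state, "quest_state"), is.finite(x))
  response <- match.arg(response, c("yes", "no"))
  psi <- psi_at(x, state$t_values, state$beta, state$guess, state$lapse,
                state$epsilon)
  state$log_post <- state$log_post +
    if (response == "yes") log(psi) else log1p(-psi)
  state$n_trials <- state$n_trials + 1L
  state
}

#' Normalised posterior masses of a QUEST state
#'
#' @param state A `quest_state`.
#' @return Numeric vector of probabilities over `state$t_values`, summing
#'   to 1.
#' @export
posterior <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  p <- exp(state$log_post - max(state$log_post))
  p / sum(p)
}

#' Posterior quantile of the threshold in log10 mM
#'
#' @param state A `quest_state`.
#' @param q Quantile orders in (0, 1) (vectorised).
#' @export
posterior_quantile <- function(state, q) {
  p <- posterior(state)
  cdf <- cumsum(p)
  vapply(q, function(qq) state$t_values[which(cdf >= qq)[1]], numeric(1))
}

#' Posterior-mean threshold estimate
#'
#' The threshold is read out as the mean of the posterior over the grid,
#' the efficient unbiased estimator for this family of procedures.
#'
#' @param state A `quest_state`.
#' @return Estimate in log10 mM.
#' @export
quest_threshold <- function(state) {
  sum(state$t_values * posterior(state))
}

#' Propose the next stimulus intensity
#'
#' Placement of the next stimulus given the current posterior. Two modes:
#'
#' * `"variance"` (default): one-step-ahead minimisation of the expected
#'   posterior variance over the candidate placements in `candidates`
#'   (normally the prepared dilution levels) — for each candidate the
#'   predictive Yes-probability and the variance of the two resulting
#'   posteriors are combined, and the candidate minimising the expectation
#'   is proposed. This is the "best placement" reading of quantile-based
#'   stimulus selection, adapted to a discrete stimulus set.
#' * `"quantile"`: the posterior quantile at order `quantile`
#'   (default 0.5, the posterior median).
#'
#' Before any trial has been run the starting intensity is proposed.
#'
#' @param state A `quest_state`.
#' @param candidates Candidate intensities in log10 mM (used by the
#'   `"variance"` mode).
#' @param placement `"variance"` or `"quantile"`.
#' @param quantile Quantile order for the `"quantile"` mode.
#' @return Proposed intensity in log10 mM.
#' @export
propose_intensity <- function(state, candidates = NULL,
                              placement = c("variance", "quantile"),
                              quantile = 0.5) {
  stopifnot(inherits(state, "quest_state"))
  placement <- match.arg(placement)
  if (state$n_trials == 0L) return(state$start)
  if (placement == "quantile") return(posterior_quantile(state, quantile))
  if (is.null(candidates)) candidates <- state$t_values
  post <- posterior(state)
  t <- state$t_values
  psi <- vapply(candidates, psi_at, numeric(length(t)), t = t,
                beta = state$beta, guess = state$guess, lapse = state$lapse,
                epsilon = state$epsilon)  # n_grid x n_cand
  wy <- psi * post            # unnormalised Yes-posteriors, one column each
  wn <- (1 - psi) * post
  sy <- colSums(wy)
  sn <- colSums(wn)
  vy <- colSums(wy * t ^ 2) / sy - (colSums(wy * t) / sy) ^ 2
  vn <- colSums(wn * t ^ 2) / sn - (colSums(wn * t) / sn) ^ 2
  ev <- sy * vy + sn * vn     # sy is the predictive P(Yes)
  # ties resolve to the first (strongest) candidate when candidates are
  # ordered strongest-first
  candidates[which.min(ev)]
}

#' Avoid presenting the identical concentration twice in a row
#'
#' If the snapped proposal equals the previously presented dilution step, the
#' presented level moves one step weaker after a Yes and one step stronger
#' after a No, clamped at the ends of the prepared series.
#'
#' @param proposed_index Snapped proposal (1 = strongest).
#' @param last_index Index presented on the previous trial (or `NA`).
#' @param last_response Response on the previous trial (`"yes"`/`"no"`).
#' @param n_steps Number of prepared dilution steps.
#' @return The index to present.
#' @export
apply_repeat_rule <- function(proposed_index, last_index, last_response,
                              n_steps) {
  if (is.na(last_index) || proposed_index != last_index) {
    return(as.integer(proposed_index))
  }
  shifted <- if (last_response == "yes") proposed_index + 1L  # weaker
             else proposed_index - 1L                          # stronger
  max(1L, min(as.integer(n_steps), as.integer(shifted)))
}

#' QUEST stopping rule
#'
#' Stop at the trial ceiling, or — once the trial floor is reached — when the
#' 5% to 95% posterior interval, expressed in linear concentration units, is
#' narrower than half the concentration presented last:
#' `10^q95 - 10^q05 < 0.5 * last_concentration` (mM).
#'
#' @param state A `quest_state`.
#' @param last_concentration Concentration presented last, in mM.
#' @return Logical.
#' @export
should_stop <- function(state, last_concentration) {
  if (state$n_trials >= state$max_trials) return(TRUE)
  if (state$n_trials < state$min_trials) return(FALSE)
  q <- posterior_quantile(state, c(0.05, 0.95))
  (10 ^ q[2] - 10 ^ q[1]) < 0.5 * last_concentration
}

#' Exclusion rule for a QUEST session
#'
#' A Yes response recorded at the weakest prepared concentration means the
#' prepared range was insufficient for this participant; the session is
#' excluded. No responses at the weakest level do not trigger exclusion.
#'
#' @param trials A QUEST trial log (tibble with `level` and `response`), or a
#'   `quest_session`.
#' @param n_steps Number of prepared dilution steps (taken from the session
#'   if one is given).
#' @return Exclusion reason code, or `NA_character_` for none.
#' @export
quest_exclude <- function(trials, n_steps = NULL) {
  if (inherits(trials, "quest_session")) {
    n_steps <- trials$series$n_steps
    trials <- trials$trials
  }
  stopifnot(!is.null(n_steps))
  if (any(trials$level == n_steps & trials$response == "yes")) {
    "yes_at_lowest"
  } else {
    NA_character_
  }
}

#' Run one QUEST threshold-estimation session
#'
#' Drives a complete grid-based Bayesian QUEST run on a prepared dilution
#' series: the first stimulus is the series' starting concentration; each
#' subsequent proposal ([propose_intensity()]) is snapped to the nearest
#' prepared concentration ([nearest_step()]) with the repeat-avoidance rule
#' ([apply_repeat_rule()]); the posterior is updated after every response;
#' the session stops per [should_stop()] (at least `min_trials`, at most
#' `max_trials`); the threshold is the posterior mean and the exclusion rule
#' of [quest_exclude()] applies.
#'
#' @inheritParams run_siam_session
#' @inheritParams quest_init
#' @inheritParams propose_intensity
#' @param grid_pad Log10 units by which the threshold grid extends beyond the
#'   prepared series range on each side.
#' @return An object of class `quest_session` (and `taste_session`).
#' @export
run_quest_session <- function(series, respond, beta = 3.5, guess = 0.01,
                              lapse = 0.01, p_target = 0.80, grain = 0.01,
                              prior_sd = 20, min_trials = 10, max_trials = 20,
                              placement = c("variance", "quantile"),
                              quantile = 0.5, grid_pad = 2,
                              start_index = series$start_index, seed = NULL,
                              participant = NA_character_,
                              session_label = NA_character_) {
  stopifnot(inherits(series, "dilution_series"))
  placement <- match.arg(placement)
  respond_fun <- as_respond_fun(respond)
  start <- series$log10_conc[start_index]
  lo <- series$log10_conc[series$n_steps] - grid_pad
  hi <- series$log10_conc[1] + grid_pad
  span <- 2 * max(start - lo, hi - start)

  runner <- function() {
    state <- quest_init(start, prior_sd = prior_sd, grain = grain,
                        span = span, beta = beta, guess = guess,
                        lapse = lapse, p_target = p_target,
                        min_trials = min_trials, max_trials = max_trials)
    last_index <- NA_integer_
    last_response <- NA_character_
    nmax <- max_trials
    levels <- integer(nmax); proposals <- numeric(nmax)
    responses <- character(nmax); post_means <- numeric(nmax)
    ci_los <- numeric(nmax); ci_his <- numeric(nmax)
    repeat {
      proposal <- propose_intensity(state, candidates = series$log10_conc,
                                    placement = placement,
                                    quantile = quantile)
      idx <- nearest_step(series, proposal)
      idx <- apply_repeat_rule(idx, last_index, last_response,
                               series$n_steps)
      lg <- series$log10_conc[idx]
      conc <- series$concentrations[idx]
      response <- respond_fun("target", conc, lg)
      state <- update_posterior(state, lg, response)
      ci <- posterior_quantile(state, c(0.05, 0.95))
      i <- state$n_trials
      levels[i] <- idx; proposals[i] <- proposal
      responses[i] <- response; post_means[i] <- quest_threshold(state)
      ci_los[i] <- ci[1]; ci_his[i] <- ci[2]
      last_index <- idx
      last_response <- response
      if (should_stop(state, conc)) break
    }
    k <- seq_len(state$n_trials)
    trials <- tibble::tibble(
      trial = k, kind = "target", level = levels[k],
      conc_mM = series$concentrations[levels[k]],
      log10_mM = series$log10_conc[levels[k]],
      proposal_log10 = proposals[k], response = responses[k],
      post_mean = post_means[k], ci_lo = ci_los[k], ci_hi = ci_his[k]
    )
    list(trials = trials, state = state)
  }
  res <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  exclusion <- quest_exclude(res$trials, series$n_steps)
  structure(
    list(method = "QUEST", series = series, trials = res$trials,
         state = res$state, n_trials = nrow(res$trials), seed = seed,
         participant = participant, session_label = session_label,
         estimate = if (is.na(exclusion)) quest_threshold(res$state)
                    else NA_real_,
         exclusion = exclusion,
         config = list(beta = beta, guess = guess, lapse = lapse,
                       p_target = p_target, grain = grain,
                       prior_sd = prior_sd, min_trials = min_trials,
                       max_trials = max_trials, placement = placement,
                       quantile = quantile, grid_pad = grid_pad,
                       start_index = start_index)),
    class = c("quest_session", "taste_session")
  )
}
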