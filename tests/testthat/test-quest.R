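# near-uniform prior on a tiny grid for hand-computed Bayes tables
flat_state <- function(t_values, ...) {
  grain <- diff(t_values)[1]
  span <- t_values[length(t_values)] - t_values[1]
  st <- quest_init(mean(range(t_values)), prior_sd = 1e6, grain = grain,
                   span = span, ...)
  expect_equal(st$t_values, t_values, tolerance = 1e-12)
  st
}

test_that("the prior is a normalised near-flat Gaussian centred on start", {
  g <- init_prior(0.5, prior_sd = 20, grain = 0.01, span = 8)
  expect_equal(sum(g$prior), 1, tolerance = 1e-9)
  expect_equal(g$t_values[which.max(g$prior)], 0.5, tolerance = 0.011)
  # sd 20 over an 8-unit span: mass ratio below exp(16/800)^-1 ~ 0.980
  expect_lt(max(g$prior) / min(g$prior), 1.05)
  expect_true(all(abs(diff(diff(g$t_values))) < 1e-12))
  expect_error(init_prior(0, prior_sd = -1), "prior_sd")
  expect_error(init_prior(0, grain = 0), "grain")
})

test_that("posterior updates match hand-computed Bayes tables", {
  # one Yes at x = 0 on the grid {-1, 0, 1}
  st <- flat_state(c(-1, 0, 1))
  st <- update_posterior(st, 0, "yes")
  psi <- vapply(c(-1, 0, 1), function(t) pf_eval(weibull_pf(t), 0),
                numeric(1))
  expect_equal(posterior(st), psi / sum(psi), tolerance = 1e-9)
  expect_equal(posterior(st), c(0.550, 0.444, 0.006), tolerance = 2e-3)
  expect_equal(quest_threshold(st), sum(c(-1, 0, 1) * psi / sum(psi)),
               tolerance = 1e-9)
  expect_equal(quest_threshold(st), -0.544, tolerance = 1e-3)

  # three trials on a 5-point grid against an explicit likelihood product
  grid5 <- seq(-1, 1, by = 0.5)
  st <- flat_state(grid5)
  xs <- c(0.2, -0.4, 0.2)
  rs <- c("yes", "no", "yes")
  for (i in 1:3) st <- update_posterior(st, xs[i], rs[i])
  lik <- rep(1, 5)
  for (i in 1:3) {
    p <- vapply(grid5, function(t) pf_eval(weibull_pf(t), xs[i]), numeric(1))
    lik <- lik * if (rs[i] == "yes") p else 1 - p
  }
  expect_equal(posterior(st), lik / sum(lik), tolerance = 1e-9)
})

test_that("updates commute and keep the posterior proper", {
  st <- flat_state(seq(-2, 2, by = 0.1))
  a <- update_posterior(update_posterior(st, 0.3, "yes"), 0.3, "no")
  b <- update_posterior(update_posterior(st, 0.3, "no"), 0.3, "yes")
  expect_equal(posterior(a), posterior(b), tolerance = 1e-12)

  # arbitrary response sequences: mass everywhere positive, sums to one
  withr::with_seed(8, {
    for (rep in 1:10) {
      st2 <- st
      for (i in 1:15) {
        st2 <- update_posterior(st2, runif(1, -2, 2),
                                sample(c("yes", "no"), 1))
      }
      p <- posterior(st2)
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_true(all(p > 0))
    }
  })
})

test_that("the posterior mean is the prior mean before any trial", {
  st <- quest_init(0.75, span = 4)
  expect_equal(quest_threshold(st), 0.75, tolerance = 1e-6)
})

test_that("stimulus proposals start at the start and track belief downward", {
  st <- quest_init(1, span = 6)
  expect_identical(propose_intensity(st), 1)
  # a run of Yes responses pushes the proposal below the mass centre
  for (i in 1:6) st <- update_posterior(st, 1 - 0.1 * (i - 1), "yes")
  prop <- propose_intensity(st, candidates = seq(-2, 2, by = 0.25))
  expect_lt(prop, quest_threshold(st))
  # quantile placement on a symmetric posterior returns its centre
  sym <- flat_state(seq(-1, 1, by = 0.01))
  sym$log_post <- dnorm(sym$t_values, 0, 0.2, log = TRUE)
  expect_equal(propose_intensity(sym, placement = "quantile"), 0,
               tolerance = 0.011)
  # proposals stay within the grid span
  expect_true(prop >= min(st$t_values) && prop <= max(st$t_values))
})

test_that("the repeat-avoidance rule shifts one step from the last level", {
  expect_identical(apply_repeat_rule(5L, 5L, "yes", 12L), 6L)   # weaker
  expect_identical(apply_repeat_rule(5L, 5L, "no", 12L), 4L)    # stronger
  expect_identical(apply_repeat_rule(5L, 4L, "yes", 12L), 5L)   # unchanged
  expect_identical(apply_repeat_rule(3L, NA_integer_, NA_character_, 12L), 3L)
  # clamped at the ends
  expect_identical(apply_repeat_rule(12L, 12L, "yes", 12L), 12L)
  expect_identical(apply_repeat_rule(1L, 1L, "no", 12L), 1L)
})

test_that("the stopping rule honours trial bounds and the linear-mM CI", {
  st <- quest_init(0, span = 6)
  concentrated <- update_posterior(st, 0, "yes")
  for (i in 1:30) {
    concentrated <- update_posterior(concentrated, 0.05 * (-1) ^ i,
                                     if (i %% 2) "yes" else "no")
  }
  concentrated$n_trials <- 9L
  expect_false(should_stop(concentrated, 1))
  concentrated$n_trials <- 20L
  expect_true(should_stop(concentrated, 1))
  # a delta-like posterior stops as soon as the floor is reached
  delta <- st
  delta$log_post <- ifelse(abs(delta$t_values) < 1e-9, 0, -1e6)
  delta$n_trials <- 10L
  expect_true(should_stop(delta, 1))
  # wide posterior at the floor does not stop
  wide <- st
  wide$n_trials <- 10L
  expect_false(should_stop(wide, 1))
  # the comparison is in linear mM: same posterior, weak last concentration
  q <- posterior_quantile(concentrated, c(0.05, 0.95))
  width_mM <- 10 ^ q[2] - 10 ^ q[1]
  concentrated$n_trials <- 10L
  expect_true(should_stop(concentrated, width_mM * 2.001 * 1))
  expect_false(should_stop(concentrated, width_mM * 1.999))
})

test_that("a Yes at the weakest prepared level excludes the session", {
  s <- make_series(100, 0.1, 10)
  tr <- tibble::tibble(level = c(4L, 7L, 10L), response = c("yes", "yes", "yes"))
  expect_identical(quest_exclude(tr, 10L), "yes_at_lowest")
  expect_true(is.na(quest_exclude(tibble::tibble(level = c(4L, 7L),
                                                 response = c("yes", "no")),
                                  10L)))
  expect_true(is.na(quest_exclude(tibble::tibble(level = 10L,
                                                 response = "no"), 10L)))
})

test_that("full sessions respect trial bounds, repeats and determinism", {
  s <- taste_series("sour")
  obs <- simulated_observer(weibull_pf(0))
  for (seed in 1:10) {
    sess <- run_quest_session(s, obs, seed = seed)
    expect_gte(sess$n_trials, 10L)
    expect_lte(sess$n_trials, 20L)
    lv <- sess$trials$level
    repeats <- which(diff(lv) == 0)
    # identical consecutive levels only at the clamped grid ends
    expect_true(all(lv[repeats] %in% c(1L, s$n_steps)))
  }
  a <- run_quest_session(s, obs, seed = 4)
  b <- run_quest_session(s, obs, seed = 4)
  expect_identical(a$trials, b$trials)
  expect_identical(a$estimate, b$estimate)
})

test_that("a deterministic threshold responder is recovered to a few steps", {
  # a hard-threshold responder is outside the assumed Weibull family, so the
  # posterior concentrates at the pseudo-true threshold near the response
  # step rather than exactly on it; recovery is to within a few grid steps
  s <- fine_series(center = 0)
  t_true <- 0.013
  sess <- run_quest_session(s, oracle_responder(t_true),
                            start_index = nearest_step(s, 1))
  expect_lt(abs(sess$estimate - t_true), 3 * step_width(s, NULL))
})
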