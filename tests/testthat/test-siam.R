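test_that("responses classify into the signal-detection 2x2", {
  expect_identical(
    classify_response(c("target", "target", "blank", "blank"),
                      c("yes", "no", "yes", "no")),
    c("hit", "miss", "false_alarm", "correct_rejection")
  )
})

test_that("stimulus schedules have exact blank composition and bounded runs", {
  withr::with_seed(5, {
    sched <- schedule_stimuli(30)
    expect_length(sched, 30)
    expect_identical(sum(sched == "blank"), 15L)
    runs <- rle(sched)
    expect_lte(max(runs$lengths[runs$values == "blank"]), 2)
  })
  # long budgets still admit valid schedules
  withr::with_seed(5, {
    long <- schedule_stimuli(200)
    expect_identical(sum(long == "blank"), 100L)
    expect_lte(max(rle(long)$lengths[rle(long)$values == "blank"]), 2)
  })
  s1 <- withr::with_seed(11, schedule_stimuli(30))
  s2 <- withr::with_seed(11, schedule_stimuli(30))
  expect_identical(s1, s2)
})

test_that("small-schedule draws cover only and all valid arrangements", {
  # 4 trials, 2 blanks, max run 2: valid arrangements are the C(4,2) = 6
  # placements minus none (no run of 3 possible with 2 blanks), so all 6
  # should appear under repeated sampling
  withr::with_seed(2, {
    draws <- replicate(600, paste(schedule_stimuli(4), collapse = ","))
  })
  expect_identical(length(unique(draws)), 6L)
  # with max run 1, adjacent blanks must vanish
  withr::with_seed(2, {
    strict <- replicate(50, schedule_stimuli(6, max_blank_run = 1))
  })
  expect_true(all(apply(strict, 2, function(s) {
    max(rle(s)$lengths[rle(s)$values == "blank"]) == 1
  })))
})

test_that("level steps follow the adjustment matrix and boost phase", {
  s <- taste_series("sour")
  obs <- simulated_observer(weibull_pf(0), false_alarm_rate = 0.25)
  sess <- run_siam_session(s, obs, seed = 101)
  tr <- sess$trials
  expect_identical(nrow(tr), 30L)
  # every applied step matches the outcome class and boost flag
  expected <- ifelse(tr$outcome == "hit", ifelse(tr$boost, -3, -1),
              ifelse(tr$outcome == "miss", 1,
              ifelse(tr$outcome == "false_alarm", 2, 0)))
  expect_identical(tr$step, as.integer(expected))
  # boost never re-activates after the first miss or false alarm
  first_off <- match(TRUE, tr$outcome %in% c("miss", "false_alarm"))
  if (!is.na(first_off) && first_off < 30) {
    expect_true(all(!tr$boost[(first_off + 1):30]))
  }
  # levels evolve as level - step, clamped to the grid
  implied <- pmax(1, pmin(s$n_steps, tr$level - tr$step))
  expect_identical(tr$level[-1], as.integer(implied[-30]))
})

test_that("reversals are sign changes between non-zero steps", {
  s <- make_series(100, 0.1, 10)
  # hand trace: steps -3, -3, +1, -1 reverse at trials 3 and 4
  tr <- siam_trial_rows(rep("target", 4), c(2L, 5L, 8L, 7L),
                        c("yes", "yes", "no", "yes"), c(-3L, -3L, 1L, -1L),
                        s)
  revs <- detect_reversals(tr)
  expect_identical(revs$trial, c(3L, 4L))
  expect_equal(revs$log10_mM, s$log10_conc[c(8, 7)])

  # monotone descent: no reversals
  mono <- siam_trial_rows(rep("target", 4), c(2L, 5L, 8L, 9L),
                          rep("yes", 4), c(-3L, -3L, -1L, -1L), s)
  expect_identical(nrow(detect_reversals(mono)), 0L)

  # zeros from correct rejections are skipped
  z <- siam_trial_rows(c("target", "blank", "blank", "target"),
                       c(3L, 4L, 4L, 4L), c("yes", "no", "no", "no"),
                       c(-1L, 0L, 0L, 1L), s)
  revs <- detect_reversals(z)
  expect_identical(revs$trial, 4L)
  expect_identical(nrow(detect_reversals(tr[0, ])), 0L)
})

test_that("reversal averaging removes odd/even leading reversals", {
  # 5 reversals (odd): drop the first, mean of the rest
  r <- reversal_threshold(c(1.0, 0.4, 0.7, 0.4, 0.7))
  expect_equal(r$estimate, 0.55)
  expect_false(r$excluded)
  # 4 reversals (even): drop the first two
  r <- reversal_threshold(c(0.9, 0.1, 0.5, 0.3))
  expect_equal(r$estimate, mean(c(0.5, 0.3)))
  # too few retained -> no estimate
  expect_true(reversal_threshold(c(0.5, 0.3))$excluded)
  expect_true(reversal_threshold(numeric())$excluded)
})

test_that("session-level exclusion rules fire in order", {
  s <- make_series(100, 0.1, 10)
  # a hit at the weakest prepared level: range insufficient
  low <- fake_siam_session(
    siam_trial_rows(rep("target", 6), c(4L, 7L, 10L, 10L, 9L, 10L),
                    c("yes", "yes", "yes", "no", "yes", "yes"),
                    c(-3L, -3L, -1L, 1L, -1L, -1L), s), s)
  expect_identical(siam_threshold(low)$exclusion, "yes_at_lowest")

  # a miss at the strongest level
  high <- fake_siam_session(
    siam_trial_rows(rep("target", 4), c(3L, 2L, 1L, 1L),
                    c("no", "no", "no", "no"), c(1L, 1L, 1L, 1L), s), s)
  expect_identical(siam_threshold(high)$exclusion, "no_at_highest")

  # all-hit interior session: no miss observed
  nomiss <- fake_siam_session(
    siam_trial_rows(c("target", "blank", "target", "blank"),
                    c(4L, 5L, 5L, 6L), c("yes", "yes", "yes", "yes"),
                    c(-1L, 2L, -1L, 2L), s), s)
  expect_identical(siam_threshold(nomiss)$exclusion, "no_miss")

  # enough reversals and a miss: a valid estimate equal to the reversal mean
  ok <- fake_siam_session(
    siam_trial_rows(rep("target", 6), c(4L, 5L, 6L, 5L, 6L, 5L),
                    c("yes", "yes", "no", "yes", "no", "yes"),
                    c(-1L, -1L, 1L, -1L, 1L, -1L), s), s)
  est <- siam_threshold(ok)
  expect_true(is.na(est$exclusion))
  rv <- detect_reversals(ok$trials)$log10_mM
  expect_equal(est$estimate, reversal_threshold(rv)$estimate)

  # the manual erratic flag overrides everything
  expect_identical(siam_threshold(fake_siam_session(ok$trials, s,
                                                    erratic = TRUE))$exclusion,
                   "erratic_responses")
})

test_that("sessions log the full budget and are estimate-xor-exclusion", {
  s <- taste_series("salty")
  obs <- simulated_observer(weibull_pf(0.8), false_alarm_rate = 0.15)
  for (seed in 1:8) {
    sess <- run_siam_session(s, obs, seed = seed)
    expect_identical(nrow(sess$trials), 30L)
    expect_true(xor(is.na(sess$estimate), is.na(sess$exclusion)))
  }
})

test_that("a session is fully reproducible from its seed", {
  s <- taste_series("sweet")
  obs <- simulated_observer(weibull_pf(0.5), false_alarm_rate = 0.2)
  a <- run_siam_session(s, obs, seed = 99)
  b <- run_siam_session(s, obs, seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$estimate, b$estimate)
})

test_that("an inattentive observer climbs off the strong end and is excluded", {
  s <- taste_series("sour")
  deaf <- simulated_observer(weibull_pf(50), false_alarm_rate = 0)
  sess <- run_siam_session(s, deaf, seed = 3)
  expect_identical(sess$exclusion, "no_at_highest")
  expect_true(any(sess$trials$clamped))
  expect_true(is.na(sess$estimate))
})

test_that("mark_erratic converts an estimate into an exclusion", {
  s <- taste_series("salty")
  obs <- simulated_observer(weibull_pf(0.8), false_alarm_rate = 0.15)
  sess <- run_siam_session(s, obs, seed = 12)
  flagged <- mark_erratic(sess)
  expect_identical(flagged$exclusion, "erratic_responses")
  expect_true(is.na(flagged$estimate))
})
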