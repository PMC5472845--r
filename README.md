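# gustadapt

Adaptive yes-no estimation of gustatory detection thresholds.

Measuring taste sensitivity is slow: stimuli are liquid dilutions applied to
the tongue, and inter-stimulus intervals of 20–30 s are needed to limit
adaptation and habituation, so every saved trial matters. `gustadapt`
implements two time-efficient adaptive yes-no procedures for estimating
detection thresholds on a prepared dilution series, together with the
simulation and analysis machinery needed to validate them and to process
test-retest study data. It is aimed at sensory scientists and clinical
researchers running taste (or smell) threshold protocols, and at
psychophysicists who want a tested reference implementation of the two
engines.

## The procedures

Stimulus intensity is log10 concentration in mM throughout. Both procedures
operate on a log-equidistant dilution series, sample 1 = strongest.

**SIAM staircase.** A single-interval adjustment-matrix staircase for yes-no
tasks with blank (deionised-water) catch trials. Half of the 30 trials are
blanks, never more than two in a row. After each trial the tracked level
moves according to the outcome:

| outcome            | step (positive = stronger) |
|--------------------|---------------------------|
| hit                | −1 (−3 until the first miss or false alarm) |
| miss               | +1 |
| false alarm        | +2 |
| correct rejection  |  0 |

This matrix tracks target performance t = p(hit) − p(fa) = 0.5; with 50%
blanks the zero-drift equilibrium is p(hit) = 0.5 + p(fa), i.e. a 75%
Yes-proportion operating point for an observer with a 25% false-alarm rate.
The threshold is the mean of the reversal concentrations after dropping the
first one (odd count) or two (even count), with exclusion rules for
insufficient range, absent misses, and erratic responding.

**QUEST.** A grid-based Bayesian procedure assuming a Weibull psychometric
function

Ψ(x) = γ + (1 − γ − λ)(1 − exp(−10^{β(x − T + ε)}))

with slope β = 3.5, asymptotes γ = λ = 0.01 (so Ψ spans [0.01, 0.99]), and
the threshold T defined at the 80% Yes point via the shift ε. A Gaussian
prior (SD 20 log10 units, effectively flat) is centred on the starting
concentration; the posterior over a 0.01-grain threshold grid is updated
after every response; proposals are placed by one-step-ahead expected
posterior-variance minimisation over the prepared levels (posterior-quantile
placement available), snapped to the nearest prepared concentration with a
repeat-avoidance rule; the run stops after 10–20 trials, earlier than 20
when the 5–95% posterior interval in mM is narrower than half the last
presented concentration. The threshold estimate is the posterior mean.

## Worked example

```r
library(gustadapt)

s <- taste_series("salty")
#> Dilution series 'sodium chloride': 12 samples, 342.231 to 0.342231 mM
#> (step width 0.273 log10), start at sample 3

obs <- simulated_observer(weibull_pf(0.3), false_alarm_rate = 0.15)
siam <- run_siam_session(s, obs, seed = 7)
siam
#> SIAM session: 30 trials
#>   threshold estimate: 0.1252 log10 mM (1.334 mM)
quest <- run_quest_session(s, obs, seed = 7)
quest
#> QUEST session: 13 trials
#>   threshold estimate: 0.2526 log10 mM (1.789 mM)
```

The simulated observer's true 80% point is 0.30 log10 mM (2.0 mM). QUEST
lands at 0.25 after 13 trials; SIAM, which tracks the lower 75% point and
uses only 15 of its 30 trials for tastants, lands at 0.13. `tidy()` returns
the trial-by-trial log, `glance()` a one-row summary, and `autoplot()` the
staircase / posterior track.

A full test-retest cohort, its pairwise-exclusion preprocessing, and the
reliability analysis:

```r
coh  <- simulate_cohort(8, seed = 42)           # 8 participants, 128 sessions
kept <- preprocess_pairs(coh$thresholds)        # drop incomplete pairs
pairs <- threshold_pairs(kept)
test_retest_corr(pairs, by = "method")
#>   method     n     r
#> 1 QUEST     29 0.995
#> 2 SIAM      30 0.979
```

(Simulated observers keep one stable threshold across sessions, so these
correlations are far higher than human test-retest values; the spread of
`r` here reflects only estimator noise.)

A command-line front end for running single sessions (interactively or in
simulation mode), re-estimating thresholds from logs, simulating cohorts,
preprocessing and validation ships at `inst/cli/gustadapt.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","gustadapt.R",package="gustadapt"))')" \
  siam --quality salty --observer 0.3,0.15 --seed 7
```

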