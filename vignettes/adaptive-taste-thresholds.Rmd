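---
title: "Adaptive yes-no taste threshold estimation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive yes-no taste threshold estimation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gustadapt)
```

`gustadapt` implements two adaptive yes-no procedures for gustatory
detection thresholds — a modified SIAM staircase and a discrete-grid QUEST —
plus the dilution-series arithmetic, simulated observers, study-design
bookkeeping and reliability analysis around them. This vignette explains the
underlying models, the tunable parameters, the numerical decisions taken
where the design was genuinely open, and the limits of what the simulation
evidence shows.

## Intensity scale and dilution series

All engine arithmetic happens on log10 concentration in mM; thresholds are
reported on that scale. A `dilution_series` is a strictly decreasing,
log-equidistant set of prepared concentrations (sample 1 = strongest).
`make_series(c_max, c_min, n)` generates entries `10^(log10(c_max) - k * d)`
with `d = (log10(c_max) - log10(c_min)) / (n - 1)`: exact endpoints, equal
spacing to machine precision. The four packaged tastant series (sucrose,
citric acid, sodium chloride, quinine hydrochloride) are stored verbatim as
published, including each session's starting concentration.

Two numerical choices live here:

* **Spacing validation.** Published concentration tables are rounded — and,
  in the weak tail of the bitter series, apparently hand-adjusted — so the
  constructor accepts adjacent log10 gaps varying by up to `spacing_tol`
  (default 0.02). Regenerating the packaged series from their endpoints
  reproduces the sodium-chloride column to 0.1% and every column to better
  than 2%; the quoted step widths (0.300, 0.269, 0.273, 0.230 log10)
  reproduce exactly.
* **Snapping and tie-breaks.** `nearest_step()` measures closeness in log10
  space, clamps out-of-range proposals, and resolves ties (within 1e-9
  log10 units, so floating-point midpoints behave deterministically) toward
  the *stronger* concentration. Rationale: a detectable stimulus keeps the
  adaptive track informative; the opposite tie-break risks an uninformative
  "No".

## The psychometric model

Both engines assume a Weibull psychometric function on the log10 scale,

$$\Psi(x) = \gamma + (1-\gamma-\lambda)\left(1 - e^{-10^{\beta (x - T + \epsilon)}}\right),$$

with slope $\beta = 3.5$, guess rate $\gamma = 0.01$ and lapse rate
$\lambda = 0.01$, so $\Psi$ spans $[0.01, 0.99]$. The stored threshold $T$
is defined as the intensity at which $\Psi$ equals the tracked target
proportion $p_t$ (0.80 for QUEST); the shift
$\epsilon = \log_{10}\{-\log(1 - (p_t-\gamma)/(1-\gamma-\lambda))\}/\beta$
is computed in closed form and cached. This makes the QUEST posterior
directly interpretable as a distribution over the 80%-Yes concentration.
Other Weibull conventions (natural-log slope, threshold at a fixed core
quantile) change only $\epsilon$, not the tracked point, so swapping
conventions would not move the estimates.

## SIAM

The adjustment matrix (strength convention, positive = stronger) is
hit −1, miss +1, false alarm +2, correct rejection 0, with hits stepping −3
during the initial *boost phase*, which ends at the first miss or false
alarm. With 50% blanks, zero expected drift gives the operating point
$p_{hit} = 0.5 + p_{fa}$ (`equilibrium_oracle()`), i.e. target performance
$t = p_{hit} - p_{fa} = 0.5$, a 75% Yes-proportion for a 25% false-alarm
observer.

Decisions the staircase literature leaves open, as resolved here:

* **Blank scheduling.** Exactly `floor(n/2)` blanks with no run of three.
  Rather than rejection-sampling shuffles (which fails for long budgets —
  at 200 trials virtually every shuffle of 100 blanks contains a 3-run),
  schedules are drawn *uniformly over the valid arrangements* by counting
  completions with dynamic programming and sampling trial by trial in
  proportion to the counts. This preserves the exact 50% composition and
  the run constraint at any budget.
* **Reversal definition.** A reversal is a trial whose applied non-zero
  step has the opposite sign to the previous applied non-zero step; the
  zero steps of correct rejections are skipped. Boost-phase steps are
  eligible anchors. The recorded reversal concentration is the tracked
  level at that trial (on false-alarm trials the presented stimulus is
  water, so the tracked level is the only meaningful concentration).
* **Threshold and exclusions.** Mean of the reversal log10 concentrations
  after dropping the first (odd count) or first two (even count). A session
  yields no estimate when fewer than two reversals remain after removal,
  when a Yes was recorded at the weakest or a No at the strongest prepared
  concentration (the staircase demanded a level beyond the range), or when
  no miss occurred. "Erratic responding" has no automated criterion and is
  a manual flag (`mark_erratic()`).
* **Averaging scale.** Reversals are averaged in log10 mM, the scale on
  which thresholds are defined and reported; an arithmetic mean in linear
  mM would be dominated by the strongest reversal.
* **Boundary handling.** Levels clamp at the grid ends and the clamp is
  recorded; the exclusion rules above, not the clamp itself, decide whether
  the session is usable. The trial budget (default 30) is configurable;
  truncated budgets are simply shorter sessions, not a separate mode.

## QUEST

The threshold grid spans the prepared series extended by ±2 log10 units at
grain 0.01 (a few hundred to ~900 points per tastant) — wide enough that
posterior mass is never truncated at realistic thresholds, small enough to
be negligible in memory. The prior is Gaussian with SD 20 *log10 units*
centred on the starting concentration: over any realistic series its
max/min mass ratio is below 1.05, i.e. effectively flat, while remaining
proper. Each Yes multiplies the posterior at every grid point $t$ by
$\Psi(x; T = t)$, each No by $1 - \Psi(x; T = t)$ (log-space accumulation,
normalised on demand); the non-degenerate asymptotes guarantee a proper
posterior after any response sequence.

* **Placement.** The "best-quantile" placement of grid-based Bayesian
  procedures is implemented as a *per-trial one-step-ahead minimisation of
  expected posterior variance* over the prepared dilution levels: for each
  candidate, the predictive Yes-probability and the variances of the two
  resulting posteriors are combined, and the minimising level is proposed.
  Computing the criterion per trial directly over the (at most ~60)
  prepared levels is cheap and well defined from trial one, whereas
  freezing a quantile order at session start is degenerate under the flat
  prior. A posterior-quantile mode (`placement = "quantile"`, default order
  0.5) is available as the simpler alternative, and the mode used is stored
  in the session's config snapshot.
* **First trial and repeats.** The first stimulus is the series' marked
  starting concentration (chosen to be clearly perceptible, and the prior
  centre). If a snapped proposal equals the previous level, the presented
  level moves one step weaker after a Yes and one step stronger after a No,
  clamped at the ends — so identical consecutive concentrations occur only
  at the grid ends.
* **Stopping.** At least 10, at most 20 trials; between those bounds the
  run stops when the 5–95% posterior interval, *transformed to linear mM*
  ($10^{q_{95}} - 10^{q_{05}}$), is narrower than half the concentration
  presented last. The rule names a concentration, so the comparison is made
  in concentration units; a log-unit variant would stop on a fixed
  *ratio* instead and behaves differently at the weak end of a series.
* **Estimate and exclusion.** The threshold is the posterior mean
  (efficient, and unbiased for matched observers in the simulations below).
  A session with any Yes at the weakest prepared concentration is excluded:
  the prepared range gave no room to bracket that participant's threshold.

## Study design and preprocessing

`build_design(n)` plans the full crossing of participants × 4 qualities ×
2 methods × 2 sessions. The constraints — methods never interleaved within
a participant, identical quality order in test and retest, orders
counterbalanced across participants — admit many schemes; the package uses
a cyclic 4 × 4 Latin square for quality orders and alternates method order
by participant parity. `preprocess_pairs()` removes the partner of any
missing threshold, so analyses see complete test-retest pairs only; removal
counts per method are attached to the result. The reliability module
computes Pearson correlations and per-cell summaries (means, SDs, paired
differences, all in log10 mM) and histograms of estimates over dilution
steps; mixed-effects modelling and post-hoc contrasts are deliberately out
of scope — the emitted tables feed directly into `lme4`/`emmeans` or any
comparable toolchain.

Interactive sessions record a No on experimenter-confirmed hesitation,
bound to an explicit keypress in the CLI; timing control is out of scope.

## The simulated observer

`simulated_observer()` responds Yes to a target at intensity $x$ with
probability $\Psi(x)$ under its own Weibull PF and to a blank with a
constant false-alarm probability; draws are Bernoulli from the session's
seeded stream, so everything downstream is bit-reproducible from one seed.
The cohort generator gives each participant × quality cell one observer
whose true threshold is drawn from a normal distribution centred on the
middle of that quality's log10 range (SD 0.6 log10 units, roughly two
dilution steps — a plausible between-subject spread for detection
thresholds) with a 15% false-alarm rate, and reuses that observer across
test, retest and both methods.

What this emulates — stable sensitivity, a stationary response criterion,
independent trials — is exactly what real participants violate in
interesting ways: no criterion drift, no adaptation or habituation across
trials, no lapses of attention beyond the constant lapse rate, no
carry-over between tastants. Passing simulations therefore validate the
*procedures* (convergence, calibration, bookkeeping), not the human
test-retest reliabilities, which depend on those non-stationarities.
Simulated test-retest correlations are correspondingly much higher than any
human cohort's.

## Validation harness and what the numbers mean

`siam_operating_point()` runs long staircases (default 500 runs × 200
trials, boost disabled) on a fine synthetic grid — 61 steps of 0.05 log10,
much finer than the prepared series, to separate convergence from
discretisation — and averages the observer's hit probability at the final
tracked level. `quest_recovery()` runs 500 QUEST sessions against matched
observers whose true thresholds are drawn from a 0.5-log10-unit window
(so results do not hinge on one threshold's alignment with the grid) and
averages each observer's Yes-probability at its posterior-mean estimate.
These sizes keep the full validation under a minute on one core while
holding Monte-Carlo error on a proportion near 0.01; `scripts/acceptance.R`
reruns both from scratch at any seed.

Two systematic effects are worth understanding when reading the output:

* **Curvature penalty.** Both metrics evaluate the PF *at a noisy
  estimate*. The Weibull is concave at the 75% and 80% points, so with
  estimator spread $\sigma$ the mean evaluated probability sits below the
  nominal target by roughly $\tfrac{1}{2}|\Psi''|\sigma^2$ even when the
  estimate itself is unbiased — about one to two percentage points at the
  spreads these procedures reach (the recovery report's `bias` column shows
  the estimates themselves are centred). The tests assert the tolerances
  (±2 points for SIAM against the closed-form equilibrium, ±3 points for
  QUEST against the 80% target) with this effect included.
* **Pseudo-true recovery.** A deterministic hard-threshold responder lies
  outside the assumed Weibull family; its posterior concentrates near the
  bracketing dilution step rather than exactly on the true threshold, so
  recovery is tested to within a few grid steps, not one grain.

## Known limitations

* The SIAM reversal convention (which trial anchors a reversal, the
  skip-zeros rule, boost-step eligibility) is the standard one but not the
  only one; alternative conventions shift individual session estimates by
  fractions of a step. It is unit-tested explicitly so a deliberate change
  will be caught.
* QUEST provides no estimate or correction of response bias in a yes-no
  task; the blank-based bias control is SIAM's alone.
* Criterion drift, adaptation and habituation observer models are not
  implemented; the validation evidence is silent about them.
* The per-trial variance-minimising placement is one defensible reading of
  "best" placement; the quantile mode exists precisely so the two can be
  compared on real protocols.
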