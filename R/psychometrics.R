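#' Weibull psychometric function anchored at a target Yes-proportion
#'
#' Constructs a yes-no Weibull psychometric function (PF)
#' \deqn{\Psi(x) = \gamma + (1-\gamma-\lambda)\,
#'   \bigl(1 - e^{-10^{\beta (x - T + \epsilon)}}\bigr)}
#' on a log10-concentration intensity scale, parameterised so that the stored
#' threshold `threshold` is the intensity at which the Yes-probability equals
#' `p_target`. The internal shift `epsilon` that achieves this is computed in
#' closed form and cached. With the defaults (slope 3.5, asymptotes 0.01 and
#' 0.99, target 0.80) the function covers the Yes-proportion interval
#' \[0.01, 0.99\] and `pf_eval(pf, threshold)` returns 0.80.
#'
#' Other Weibull conventions (e.g. natural-log slope, or thresholds defined at
#' a fixed quantile of the core Weibull) differ from this one only through
#' `epsilon`: the tracked `p_target` point, which is all the adaptive engines
#' use, is unaffected by the convention.
#'
#' @param threshold Intensity (log10 mM) at which \eqn{\Psi} equals `p_target`.
#' @param beta Slope of the Weibull on the log10 scale (dimensionless).
#' @param guess Lower asymptote \eqn{\gamma} (false-alarm floor).
#' @param lapse Lapse rate \eqn{\lambda}; the upper asymptote is
#'   \eqn{1-\lambda}.
#' @param p_target Yes-proportion at which the threshold is defined; must lie
#'   strictly between `guess` and `1 - lapse`.
#' @return An object of class `weibull_pf`.
#' @examples
#' pf <- weibull_pf(threshold = 0)
#' pf_eval(pf, 0)      # 0.80
#' pf_eval(pf, -10)    # ~0.01, the lower asymptote
#' @export
weibull_pf <- function(threshold, beta = 3.5, guess = 0.01, lapse = 0.01,
                       p_target = 0.80) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold),
            is.numeric(beta), beta > 0)
  if (!(0 <= guess && guess < p_target && p_target < 1 - lapse &&
        1 - lapse <= 1)) {
    stop("require 0 <= guess < p_target < 1 - lapse <= 1", call. = FALSE)
  }
  structure(
    list(threshold = threshold, beta = beta, guess = guess, lapse = lapse,
         p_target = p_target,
         epsilon = epsilon_shift(beta, guess, lapse, p_target)),
    class = "weibull_pf"
  )
}

#' @export
print.weibull_pf <- function(x, ...) {
  cat(sprintf(
    "Weibull PF: threshold %.4f log10 mM at p = %.2f (beta %.2f, asymptotes [%.2f, %.2f])\n",
    x$threshold, x$p_target, x$beta, x$guess, 1 - x$lapse))
  invisible(x)
}

#' Shift placing the Weibull threshold at the target Yes-proportion
#'
#' Solves \eqn{\Psi(T) = p} for the log10-unit shift \eqn{\epsilon} in the
#' Weibull form used by [weibull_pf()]:
#' \eqn{\epsilon = \log_{10}\{-\log(1 - (p-\gamma)/(1-\gamma-\lambda))\}/\beta}.
#' The shift scales as \eqn{1/\beta}.
#'
#' @inheritParams weibull_pf
#' @return Shift in log10 units.
#' @export
epsilon_shift <- function(beta, guess = 0.01, lapse = 0.01, p_target = 0.80) {
  if (!(guess < p_target && p_target < 1 - lapse)) {
    stop("p_target must lie strictly between guess and 1 - lapse",
         call. = FALSE)
  }
  log10(-log(1 - (p_target - guess) / (1 - guess - lapse))) / beta
}

#' Evaluate a Weibull psychometric function
#'
#' @param pf A [weibull_pf()] object.
#' @param x Intensities in log10 mM (vectorised).
#' @return Yes-probabilities in `[guess, 1 - lapse]`.
#' @export
pf_eval <- function(pf, x) {
  stopifnot(inherits(pf, "weibull_pf"))
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  pf$guess + (1 - pf$guess - pf$lapse) *
    (1 - exp(-10 ^ (pf$beta * (x - pf$threshold + pf$epsilon))))
}

#' Invert a Weibull psychometric function
#'
#' @param pf A [weibull_pf()] object.
#' @param p Yes-probabilities strictly inside `(guess, 1 - lapse)`.
#' @return Intensities x (log10 mM) with `pf_eval(pf, x) == p`.
#' @export
pf_invert <- function(pf, p) {
  stopifnot(inherits(pf, "weibull_pf"))
  if (any(p <= pf$guess | p >= 1 - pf$lapse)) {
    stop("p must lie strictly inside (guess, 1 - lapse)", call. = FALSE)
  }
  pf$threshold - pf$epsilon +
    log10(-log(1 - (p - pf$guess) / (1 - pf$guess - pf$lapse))) / pf$beta
}

#' Simulated yes-no observer
#'
#' A generative response model standing in for a participant: on target trials
#' the Yes-probability follows the observer's Weibull PF at the presented
#' intensity; on blank (water) trials Yes occurs with a constant false-alarm
#' probability. Responses are Bernoulli draws from the R random stream of the
#' calling context; session drivers seed that stream, so equal seeds reproduce
#' identical response sequences.
#'
#' @param pf A [weibull_pf()] describing the observer's true sensitivity.
#' @param false_alarm_rate Probability of Yes on a blank, in `[0, 1)`.
#' @return An object of class `sim_observer` that can be called by
#'   [observer_respond()] or passed to the `run_*_session()` drivers.
#' @export
simulated_observer <- function(pf, false_alarm_rate = 0) {
  stopifnot(inherits(pf, "weibull_pf"),
            is.numeric(false_alarm_rate), length(false_alarm_rate) == 1,
            false_alarm_rate >= 0, false_alarm_rate < 1)
  structure(list(pf = pf, false_alarm_rate = false_alarm_rate),
            class = "sim_observer")
}

#' @export
print.sim_observer <- function(x, ...) {
  cat(sprintf(
    "Simulated observer: true threshold %.4f log10 mM, false-alarm rate %.2f\n",
    x$pf$threshold, x$false_alarm_rate))
  invisible(x)
}

#' Draw one response from a simulated observer
#'
#' @param observer A [simulated_observer()].
#' @param kind `"target"` or `"blank"`.
#' @param x Intensity in log10 mM; required for targets, ignored for blanks.
#' @return `"yes"` or `"no"`.
#' @export
observer_respond <- function(observer, kind, x = NULL) {
  stopifnot(inherits(observer, "sim_observer"))
  kind <- match.arg(kind, c("target", "blank"))
  p <- if (kind == "target") {
    if (is.null(x)) stop("target trials need an intensity x", call. = FALSE)
    pf_eval(observer$pf, x)
  } else {
    observer$false_alarm_rate
  }
  if (runif(1) < p) "yes" else "no"
}
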