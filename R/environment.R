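#' Define the decision environment
#'
#' An environment describes the binary world an agent must classify: a
#' "good" or a "bad" state (e.g. a fruiting tree of good or bad quality),
#' each emitting binary evidence (e.g. green vs. pale fruit husks) at a
#' state-dependent rate, together with the fitness stakes of the decision.
#'
#' @param eps_good Probability in (0, 1) that a piece of evidence reads 1
#'   (a "green husk") when the true state is good.
#' @param eps_bad Probability in (0, 1) that a piece of evidence reads 1
#'   when the true state is bad. Must be smaller than `eps_good`.
#' @param prior_good Probability that the true state is good; the default
#'   half-and-half prior makes the two hypotheses a priori symmetric.
#' @param benefit Fitness benefit B of a correct decision, in fitness units.
#' @param c_time Baseline cost per sample (per unit of decision time),
#'   independent of effort: predation risk, opportunity cost and the like.
#'
#' @return An object of class `sprt_environment`: a validated list with the
#'   five fields above.
#' @examples
#' env <- sprt_environment()
#' env
#' @seealso [sprt_policy()], [adjusted_params()], [simulate_ensemble()]
#' @export
sprt_environment <- function(eps_good = 0.75, eps_bad = 0.25,
                             prior_good = 0.5, benefit = 10,
                             c_time = 0.02) {
  stopifnot(
    is.numeric(eps_good), length(eps_good) == 1L,
    is.numeric(eps_bad), length(eps_bad) == 1L,
    is.numeric(prior_good), length(prior_good) == 1L,
    is.numeric(benefit), length(benefit) == 1L,
    is.numeric(c_time), length(c_time) == 1L
  )
  if (!(eps_bad > 0 && eps_good < 1 && eps_bad < eps_good)) {
    abort(paste0(
      "`eps_good` and `eps_bad` must satisfy 0 < eps_bad < eps_good < 1 ",
      "(got eps_good = ", eps_good, ", eps_bad = ", eps_bad, ")."
    ))
  }
  if (prior_good <= 0 || prior_good >= 1) {
    abort("`prior_good` must lie strictly between 0 and 1.")
  }
  if (benefit < 0) abort("`benefit` must be non-negative.")
  if (c_time < 0) abort("`c_time` must be non-negative.")
  structure(
    list(
      eps_good = eps_good, eps_bad = eps_bad, prior_good = prior_good,
      benefit = benefit, c_time = c_time
    ),
    class = "sprt_environment"
  )
}

#' @export
print.sprt_environment <- function(x, ...) {
  cat("<sprt_environment>\n")
  cat(sprintf("  eps_good = %g, eps_bad = %g, prior_good = %g\n",
              x$eps_good, x$eps_bad, x$prior_good))
  cat(sprintf("  benefit = %g, c_time = %g\n", x$benefit, x$c_time))
  invisible(x)
}

#' Define an agent's decision policy
#'
#' A policy is a pair (theta, phi): `theta` sets the symmetric log-odds
#' stopping thresholds of the sequential probability ratio test, and `phi`
#' is the effort level -- the probability that a sample is perceived
#' error-free. With probability `1 - phi` the perceived value is replaced
#' by a fair coin flip.
#'
#' @param theta Threshold parameter, strictly between 0.5 and 1. The
#'   stopping boundaries are `+/- log(theta / (1 - theta))`; the closer
#'   `theta` is to 1, the more evidence is gathered before deciding.
#' @param phi Effort level in `[0, 1)`: probability of an error-free
#'   observation. `phi = 1` is excluded because its effort cost diverges
#'   under the hyperbolic cost curve (see [cost_from_phi()]).
#'
#' @return An object of class `sprt_policy`.
#' @examples
#' sprt_policy(theta = 0.88, phi = 0.62)
#' @export
sprt_policy <- function(theta, phi) {
  check_theta(theta)
  check_phi(phi)
  structure(list(theta = theta, phi = phi), class = "sprt_policy")
}

#' @export
print.sprt_policy <- function(x, ...) {
  cat(sprintf("<sprt_policy> theta = %g, phi = %g\n", x$theta, x$phi))
  invisible(x)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta <= 0.5) || any(theta >= 1)) {
    abort("`theta` must lie strictly between 0.5 and 1.")
  }
  invisible(theta)
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || any(!is.finite(phi)) ||
      any(phi < 0) || any(phi >= 1)) {
    abort("`phi` must lie in [0, 1).")
  }
  invisible(phi)
}

#' Effective evidence distributions under perceptual error
#'
#' With effort level `phi`, a sample is read correctly with probability
#' `phi` and replaced by a fair coin flip otherwise. The effective
#' probability that a sample reads 1 is therefore the mixture
#' `phi * eps + (1 - phi) / 2` under either state. A self-aware agent uses
#' these adjusted probabilities in the SPRT, giving log-likelihood weights
#' `w_plus = log(eps_good_eff / eps_bad_eff)` for a sample of 1 and
#' `w_minus = log((1 - eps_good_eff) / (1 - eps_bad_eff))` for a sample
#' of 0.
#'
#' At `phi = 0` perception is pure noise: both effective distributions
#' collapse to 1/2 and both weights are zero, so no amount of evidence can
#' ever move the decision variable.
#'
#' @param phi Effort level in `[0, 1)`.
#' @param env An [sprt_environment()].
#' @return A list of class `sprt_perception` with fields `eps_good_eff`,
#'   `eps_bad_eff`, `w_plus` and `w_minus`.
#' @examples
#' adjusted_params(0.8, sprt_environment(eps_good = 0.75, eps_bad = 0.25))
#' @export
adjusted_params <- function(phi, env) {
  check_phi(phi)
  stopifnot(inherits(env, "sprt_environment"))
  eps_good_eff <- phi * env$eps_good + (1 - phi) / 2
  eps_bad_eff <- phi * env$eps_bad + (1 - phi) / 2
  structure(
    list(
      eps_good_eff = eps_good_eff,
      eps_bad_eff = eps_bad_eff,
      w_plus = log(eps_good_eff / eps_bad_eff),
      w_minus = log((1 - eps_good_eff) / (1 - eps_bad_eff))
    ),
    class = "sprt_perception"
  )
}

#' Log-odds stopping boundary for a threshold parameter
#'
#' @param theta Threshold parameter in (0.5, 1).
#' @return The boundary magnitude `log(theta / (1 - theta))`.
#' @export
decision_threshold <- function(theta) {
  check_theta(theta)
  log(theta / (1 - theta))
}

#' Apply the SPRT stopping rule to a decision variable
#'
#' Decides "good" when the accumulated log-likelihood sum `y` has reached
#' the upper boundary `log(theta/(1 - theta))`, "bad" at the lower boundary
#' `-log(theta/(1 - theta))`, and "continue" otherwise. The comparisons
#' (`>=` / `<=`) carry a relative slack of 1e-9: a sum that lands
#' numerically on the boundary counts as crossing even when rounding has
#' displaced it by a few ulps. The absorption oracles apply the same rule,
#' so simulator and oracle agree on boundary-aligned walks (which arise
#' whenever `theta` equals an effective evidence probability of the grid).
#'
#' @param y Numeric vector of decision-variable values (log-likelihood
#'   sums).
#' @param theta Threshold parameter in (0.5, 1).
#' @return Character vector over `{"good", "bad", "continue"}`.
#' @examples
#' decide(c(0, 1.2, -1.2), theta = 0.75)
#' @export
decide <- function(y, theta) {
  thr <- decision_threshold(theta)
  slack <- boundary_slack(thr)
  out <- rep("continue", length(y))
  out[y >= thr - slack] <- "good"
  out[y <= -(thr - slack)] <- "bad"
  out
}

# Shared boundary tolerance: decide(), the simulation engine and the
# absorption oracles must all treat a numerically boundary-aligned sum as
# crossing, or rounding makes them disagree about walks whose step divides
# the threshold exactly.
boundary_slack <- function(thr) 1e-9 * max(1, abs(thr))
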