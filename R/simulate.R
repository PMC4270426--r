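#' Perceive a binary sample through a noisy channel
#'
#' With probability `phi` the true value is read correctly; otherwise the
#' reading is replaced by a fair coin flip. The total probability of
#' reading the true value is therefore `phi + (1 - phi) / 2`.
#'
#' Draws come from R's global random stream. Two uniforms are consumed per
#' sample (one for the corruption event, one for the coin flip) whether or
#' not the corruption occurs, so scalar and vectorised simulations consume
#' identical streams.
#'
#' @param true_husk Integer vector of 0/1 true sample values.
#' @param phi Effort level in `[0, 1)`.
#' @return Integer vector of perceived 0/1 values.
#' @examples
#' set.seed(1)
#' mean(perceive_sample(rep(1L, 1e4), phi = 0.8))  # about 0.9
#' @export
perceive_sample <- function(true_husk, phi) {
  check_phi(phi)
  if (any(is.na(true_husk)) || !all(true_husk %in% c(0L, 1L))) {
    abort("`true_husk` must contain only 0 and 1.")
  }
  n <- length(true_husk)
  keep <- runif(n) < phi
  noise <- as.integer(runif(n) < 0.5)
  ifelse(keep, as.integer(true_husk), noise)
}

#' Run a single sequential decision trial
#'
#' Draws a true state from the prior, then repeatedly draws a piece of
#' evidence (1 with probability `eps_good` or `eps_bad` according to the
#' true state), perceives it through the noisy channel at effort `phi`,
#' adds the corresponding log-likelihood weight to the decision variable
#' and stops at the first threshold crossing. If no boundary has been
#' reached after `t_max` samples the trial is recorded as undecided; with
#' `phi = 0` the weights are zero and this is guaranteed to happen.
#'
#' Uses R's global random stream; seed with [set.seed()] for
#' reproducibility (the ensemble wrapper [simulate_ensemble()] manages the
#' seed itself).
#'
#' @param env An [sprt_environment()].
#' @param policy An [sprt_policy()].
#' @param t_max Truncation cap on the number of samples; at least 1.
#' @return A one-row tibble with columns `true_state` ("good"/"bad"),
#'   `decision` ("good"/"bad"/"undecided"), `n_samples` and `correct`
#'   (`NA` when undecided).
#' @export
run_trial <- function(env, policy, t_max = 10000L) {
  stopifnot(inherits(env, "sprt_environment"), inherits(policy, "sprt_policy"))
  stopifnot(t_max >= 1)
  ap <- adjusted_params(policy$phi, env)
  thr <- decision_threshold(policy$theta)
  true_good <- runif(1) < env$prior_good
  p_husk <- if (true_good) env$eps_good else env$eps_bad
  y <- 0
  decision <- "undecided"
  n <- 0L
  while (n < t_max) {
    n <- n + 1L
    husk <- as.integer(runif(1) < p_husk)
    s <- perceive_sample(husk, policy$phi)
    y <- y + if (s == 1L) ap$w_plus else ap$w_minus
    d <- decide(y, policy$theta)
    if (d != "continue") {
      decision <- d
      break
    }
  }
  true_state <- if (true_good) "good" else "bad"
  tibble(
    true_state = true_state,
    decision = decision,
    n_samples = n,
    correct = if (decision == "undecided") NA else decision == true_state
  )
}

#' Simulate an ensemble of decision trials
#'
#' Runs `n_trials` independent trials of [run_trial()] (in a vectorised
#' step-synchronous sweep that consumes the same random draws per trial)
#' and aggregates them. Undecided (truncated) trials are excluded from the
#' numerator and denominator of `p_correct` but contribute `t_max` samples
#' to `mean_dt`; both counts are reported so the choice is visible.
#'
#' @param env An [sprt_environment()].
#' @param policy An [sprt_policy()].
#' @param n_trials Ensemble size, at least 1.
#' @param seed Optional integer seed. When supplied, the global RNG state
#'   is restored afterwards and the same seed reproduces the summary
#'   bit-for-bit.
#' @param t_max Truncation cap per trial.
#' @return A one-row tibble of class `sprt_ensemble` with columns
#'   `p_correct`, `mean_dt`, `n_trials`, `n_decided`, `n_correct`,
#'   `n_truncated` and `n_true_good`.
#' @examples
#' env <- sprt_environment()
#' pol <- sprt_policy(theta = 0.85, phi = 0.9)
#' simulate_ensemble(env, pol, n_trials = 1000, seed = 1)
#' @export
simulate_ensemble <- function(env, policy, n_trials, seed = NULL,
                              t_max = 10000L) {
  stopifnot(inherits(env, "sprt_environment"), inherits(policy, "sprt_policy"))
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1)
  stopifnot(t_max >= 1)
  n_trials <- as.integer(n_trials)
  res <- with_seed(seed, simulate_trials_engine(env, policy, n_trials, t_max))
  n_decided <- sum(res$decision != 0L)
  n_correct <- sum(res$correct, na.rm = TRUE)
  out <- tibble(
    p_correct = if (n_decided > 0) n_correct / n_decided else NA_real_,
    mean_dt = mean(res$n_samples),
    n_trials = n_trials,
    n_decided = n_decided,
    n_correct = n_correct,
    n_truncated = n_trials - n_decided,
    n_true_good = sum(res$true_good)
  )
  class(out) <- c("sprt_ensemble", class(out))
  attr(out, "env") <- env
  attr(out, "policy") <- policy
  attr(out, "t_max") <- t_max
  out
}

# Vectorised trial engine. For each active trial and step it draws, in
# order: husk, corruption event, coin flip -- the same three uniforms per
# (trial, step) as run_trial(), so a one-trial ensemble replays run_trial
# exactly for the same seed.
simulate_trials_engine <- function(env, policy, n, t_max) {
  ap <- adjusted_params(policy$phi, env)
  thr <- decision_threshold(policy$theta)
  true_good <- runif(n) < env$prior_good
  # Zero weights can never cross a positive boundary: every trial truncates.
  if (ap$w_plus <= 0) {
    return(list(
      true_good = true_good,
      decision = rep(0L, n),
      n_samples = rep(as.integer(t_max), n),
      correct = rep(NA, n)
    ))
  }
  p_husk <- ifelse(true_good, env$eps_good, env$eps_bad)
  slack <- boundary_slack(thr)
  y <- numeric(n)
  decision <- rep(0L, n) # 0 continue, +1 good, -1 bad
  n_samples <- rep(as.integer(t_max), n)
  active <- seq_len(n)
  t <- 0L
  while (length(active) > 0L && t < t_max) {
    t <- t + 1L
    m <- length(active)
    husk <- runif(m) < p_husk[active]
    keep <- runif(m) < policy$phi
    noise <- runif(m) < 0.5
    s <- ifelse(keep, husk, noise)
    y[active] <- y[active] + ifelse(s, ap$w_plus, ap$w_minus)
    hit_up <- y[active] >= thr - slack
    hit_lo <- y[active] <= -(thr - slack) & !hit_up
    done <- hit_up | hit_lo
    if (any(done)) {
      idx <- active[done]
      decision[idx] <- ifelse(hit_up[done], 1L, -1L)
      n_samples[idx] <- t
      active <- active[!done]
    }
  }
  correct <- rep(NA, n)
  dec <- decision != 0L
  correct[dec] <- (decision[dec] == 1L) == true_good[dec]
  list(
    true_good = true_good, decision = decision,
    n_samples = n_samples, correct = correct
  )
}

#' @export
print.sprt_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sprt_ensemble> %d trials: p_correct = %.4f, mean_dt = %.3f, truncated = %d\n",
    x$n_trials, x$p_correct, x$mean_dt, x$n_truncated
  ))
  invisible(x)
}

#' @rdname simulate_ensemble
#' @param x An `sprt_ensemble` object.
#' @param ... Unused.
#' @export
tidy.sprt_ensemble <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sprt_ensemble")
  as_tibble(out)
}
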