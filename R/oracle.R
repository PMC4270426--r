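#' Recast an SPRT decision problem as a bounded random walk
#'
#' Conditional on the true state, the decision variable performs a random
#' walk with two step sizes (`w_plus` with probability `p_up`, `w_minus`
#' otherwise) between absorbing boundaries at `+/- threshold`. The walk is
#' oriented so that upper absorption is the *correct* decision: for the
#' bad state the walk is mirrored (steps and step probabilities flipped),
#' which leaves absorption probabilities and times unchanged.
#'
#' @param p_up Probability of a `w_plus` step, given the true state.
#' @param w_plus,w_minus Step sizes; `w_plus > 0 > w_minus` for an
#'   informative walk.
#' @param threshold Boundary magnitude `log(theta / (1 - theta))`.
#' @return An object of class `sprt_walk`.
#' @seealso [as_walk()] to build the walk from an environment and policy,
#'   [ruin_closed_form()] and [dp_absorption()] to solve it.
#' @export
walk_spec <- function(p_up, w_plus, w_minus, threshold) {
  stopifnot(
    is.numeric(p_up), length(p_up) == 1L, p_up >= 0, p_up <= 1,
    is.numeric(w_plus), length(w_plus) == 1L,
    is.numeric(w_minus), length(w_minus) == 1L,
    is.numeric(threshold), length(threshold) == 1L, threshold > 0
  )
  structure(
    list(p_up = p_up, w_plus = w_plus, w_minus = w_minus,
         threshold = threshold),
    class = "sprt_walk"
  )
}

#' @rdname walk_spec
#' @param env An [sprt_environment()].
#' @param policy An [sprt_policy()].
#' @param state Which true state the walk is conditioned on.
#' @export
as_walk <- function(env, policy, state = c("good", "bad")) {
  state <- match.arg(state)
  ap <- adjusted_params(policy$phi, env)
  thr <- decision_threshold(policy$theta)
  if (state == "good") {
    walk_spec(ap$eps_good_eff, ap$w_plus, ap$w_minus, thr)
  } else {
    # Mirror the bad-state walk so that "up" is the correct direction.
    walk_spec(1 - ap$eps_bad_eff, -ap$w_minus, -ap$w_plus, thr)
  }
}

# Classical gambler's ruin on the integer lattice: walk of +/-1 steps from
# 0 with up-probability p, absorbed at +a (correct) or -a.
lattice_ruin <- function(p, a) {
  stopifnot(a >= 1)
  if (abs(p - 0.5) < 1e-15) {
    return(list(p_correct = 0.5, expected_time = a^2))
  }
  r <- (1 - p) / p
  p_correct <- 1 / (1 + r^a)
  expected_time <- (a - 2 * a * p_correct) / ((1 - p) - p)
  list(p_correct = p_correct, expected_time = expected_time)
}

#' Closed-form absorption for a symmetric lattice walk
#'
#' When the two step sizes are mirror images (`w_minus = -w_plus`, as in
#' any environment with `eps_bad = 1 - eps_good`) and the boundary is an
#' exact integer multiple `a` of the step, the decision variable is a
#' textbook gambler's-ruin walk started midway between boundaries at
#' `+/- a`. With odds ratio `q/p = (1 - p_up)/p_up`, the probability of
#' absorbing at the correct boundary is `1 / (1 + (q/p)^a)` and the
#' expected absorption time is `(a - 2 a p_correct) / (q - p)` (or `a^2`
#' for the unbiased walk).
#'
#' @param walk An [walk_spec()] object.
#' @return A list with `p_correct` and `expected_time`.
#' @section Errors: Signals an error of class `sprteffort_not_lattice`
#'   when the walk is asymmetric or the boundary is not integer-aligned
#'   (tolerance 1e-9); use [dp_absorption()] for such walks.
#' @examples
#' w <- walk_spec(0.75, log(3), -log(3), 2 * log(3))
#' ruin_closed_form(w)  # p_correct = 0.9, expected_time = 3.2
#' @export
ruin_closed_form <- function(walk) {
  stopifnot(inherits(walk, "sprt_walk"))
  if (walk$w_plus <= 0 || abs(walk$w_plus + walk$w_minus) > 1e-9) {
    abort(
      "Walk is not a symmetric lattice walk; use dp_absorption().",
      class = "sprteffort_not_lattice"
    )
  }
  a_real <- walk$threshold / walk$w_plus
  a <- round(a_real)
  if (a < 1 || abs(a_real - a) > 1e-9) {
    abort(
      paste0(
        "Boundary is not an integer multiple of the step (",
        "threshold/w_plus = ", format(a_real), "); use dp_absorption()."
      ),
      class = "sprteffort_not_lattice"
    )
  }
  lattice_ruin(walk$p_up, a)
}

#' Absorption probabilities by forward probability propagation
#'
#' Solves an arbitrary two-step bounded walk numerically: mass is
#' propagated over the reachable decision-variable values, indexed by the
#' number of up-steps taken (never by the rounded value of the decision
#' variable, so no floating-point state collisions are possible), and
#' absorbed mass is removed at each step using the boundary comparisons
#' of [decide()] with a relative slack of 1e-9, so that walks whose
#' boundary is an exact multiple of a step absorb on the boundary despite
#' rounding in the state values. Handles boundary overshoot and asymmetric
#' step sizes. Mass still in flight after `t_max` steps is reported as
#' `unabsorbed_mass`, and contributes `t_max` to `expected_time` (the
#' same convention as truncated simulated trials).
#'
#' @param walk An [walk_spec()] object (oriented so upper = correct).
#' @param t_max Maximum number of steps to propagate; at least 1.
#' @return A list with `p_correct` (mass absorbed at the upper boundary),
#'   `p_wrong` (lower boundary), `expected_time`, `expected_time_sq` (the
#'   second moment of the absorption time, useful for standard-error
#'   bands around simulated decision times) and `unabsorbed_mass`.
#' @examples
#' w <- walk_spec(0.7, log(0.7 / 0.4), log(0.3 / 0.6), log(4))
#' dp_absorption(w, t_max = 500)
#' @export
dp_absorption <- function(walk, t_max = 10000L) {
  stopifnot(inherits(walk, "sprt_walk"), t_max >= 1)
  p <- walk$p_up
  q <- 1 - p
  wp <- walk$w_plus
  wm <- walk$w_minus
  thr <- walk$threshold
  slack <- boundary_slack(thr)
  mass <- 1 # mass over u = 0..t-1 up-steps before step t
  p_correct <- 0
  p_wrong <- 0
  expected_time <- 0
  expected_time_sq <- 0
  t_used <- 0L
  for (t in seq_len(t_max)) {
    t_used <- t
    mass <- q * c(mass, 0) + p * c(0, mass) # now indexed u = 0..t
    u <- 0:t
    y <- u * wp + (t - u) * wm
    hit_up <- y >= thr - slack
    hit_lo <- y <= -(thr - slack) & !hit_up
    absorbed <- hit_up | hit_lo
    if (any(absorbed)) {
      p_correct <- p_correct + sum(mass[hit_up])
      p_wrong <- p_wrong + sum(mass[hit_lo])
      expected_time <- expected_time + t * sum(mass[absorbed])
      expected_time_sq <- expected_time_sq + t^2 * sum(mass[absorbed])
      mass[absorbed] <- 0
    }
    if (sum(mass) < 1e-14) {
      mass <- numeric(0)
      break
    }
  }
  unabsorbed <- if (length(mass)) sum(mass) else 0
  expected_time <- expected_time + unabsorbed * t_max
  expected_time_sq <- expected_time_sq + unabsorbed * t_max^2
  list(
    p_correct = p_correct, p_wrong = p_wrong,
    expected_time = expected_time, expected_time_sq = expected_time_sq,
    unabsorbed_mass = unabsorbed
  )
}

#' Exact decision performance without simulation
#'
#' Computes the proportion of correct decisions and the mean decision time
#' for a policy by solving the conditional random walks analytically,
#' weighting the two true states by the prior. Symmetric environments
#' (`eps_bad = 1 - eps_good`) reduce to a lattice walk whose boundary sits
#' exactly `ceiling(threshold / w_plus)` steps away, solved in closed
#' form; other environments are solved by [dp_absorption()].
#'
#' @param env An [sprt_environment()].
#' @param policy An [sprt_policy()].
#' @param t_max Step cap for the dynamic-programming solver (and the
#'   validity cutoff: if any probability mass is still unabsorbed the cell
#'   is flagged invalid).
#' @return A one-row tibble with `p_correct` (among decided mass),
#'   `mean_dt`, `unabsorbed_mass` and `valid`.
#' @export
oracle_summary <- function(env, policy, t_max = 10000L) {
  stopifnot(inherits(env, "sprt_environment"), inherits(policy, "sprt_policy"))
  ap <- adjusted_params(policy$phi, env)
  if (ap$w_plus <= 0) {
    return(tibble(
      p_correct = NA_real_, mean_dt = Inf,
      unabsorbed_mass = 1, valid = FALSE
    ))
  }
  thr <- decision_threshold(policy$theta)
  symmetric <- abs(ap$w_plus + ap$w_minus) <= 1e-9
  if (symmetric) {
    # First crossing of a +/-w lattice walk happens exactly at
    # ceiling(thr / w) steps from the origin, overshoot-free.
    a <- ceiling(thr / ap$w_plus - 1e-9)
    res <- lattice_ruin(ap$eps_good_eff, max(a, 1))
    return(tibble(
      p_correct = res$p_correct, mean_dt = res$expected_time,
      unabsorbed_mass = 0, valid = TRUE
    ))
  }
  good <- dp_absorption(as_walk(env, policy, "good"), t_max)
  bad <- dp_absorption(as_walk(env, policy, "bad"), t_max)
  pg <- env$prior_good
  unabs <- pg * good$unabsorbed_mass + (1 - pg) * bad$unabsorbed_mass
  decided <- 1 - unabs
  p_correct <- if (decided > 0) {
    (pg * good$p_correct + (1 - pg) * bad$p_correct) / decided
  } else {
    NA_real_
  }
  tibble(
    p_correct = p_correct,
    mean_dt = pg * good$expected_time + (1 - pg) * bad$expected_time,
    unabsorbed_mass = unabs,
    valid = unabs <= 1e-9
  )
}
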