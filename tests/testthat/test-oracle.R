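test_that("gambler's-ruin closed form reproduces textbook absorption values", {
  # unbiased walk, boundary 3 steps away: even odds, E[T] = a^2
  un <- ruin_closed_form(walk_spec(0.5, 1, -1, 3))
  expect_equal(un$p_correct, 0.5)
  expect_equal(un$expected_time, 9)
  # one-step boundary: the first sample decides
  one <- ruin_closed_form(walk_spec(0.75, log(3), -log(3), log(3)))
  expect_equal(one$p_correct, 0.75)
  expect_equal(one$expected_time, 1)
  # two-step boundary: P = 1/(1 + (1/3)^2) = 0.9, E[T] = 3.2
  two <- ruin_closed_form(walk_spec(0.75, log(3), -log(3), 2 * log(3)))
  expect_equal(two$p_correct, 0.9)
  expect_equal(two$expected_time, 3.2)
})

test_that("two-step-boundary absorption agrees with exhaustive path enumeration", {
  # independent oracle: enumerate all +/-1 paths from 0 with boundaries at
  # +/-2, tracking the surviving distribution; the tail beyond length 20
  # is bounded by a geometric sum (survival mass halves every 2 steps).
  p <- 0.75
  enum_paths <- function(p, horizon) {
    states <- c(`0` = 1) # position -> probability, |position| < 2
    p_up_abs <- 0
    e_t <- 0
    for (t in seq_len(horizon)) {
      nxt <- c(`-1` = 0, `0` = 0, `1` = 0)
      for (pos in names(states)) {
        m <- states[[pos]]
        for (step in c(1, -1)) {
          np <- as.numeric(pos) + step
          pr <- m * if (step == 1) p else 1 - p
          if (np >= 2) {
            p_up_abs <- p_up_abs + pr
            e_t <- e_t + t * pr
          } else if (np <= -2) {
            e_t <- e_t + t * pr
          } else {
            nxt[as.character(np)] <- nxt[as.character(np)] + pr
          }
        }
      }
      states <- nxt[nxt > 0]
    }
    list(p_up = p_up_abs, e_t = e_t, leftover = sum(states))
  }
  en <- enum_paths(p, 40)
  expect_lt(en$leftover, 1e-8)
  expect_equal(en$p_up, 0.9, tolerance = 1e-7)
  expect_equal(en$e_t, 3.2, tolerance = 1e-5)
})

test_that("dynamic programming matches the closed form on lattice walks", {
  walks <- list(
    walk_spec(0.5, 1, -1, 3),
    walk_spec(0.75, log(3), -log(3), log(3)),
    walk_spec(0.75, log(3), -log(3), 2 * log(3))
  )
  for (w in walks) {
    cf <- ruin_closed_form(w)
    dp <- dp_absorption(w, t_max = 5000)
    expect_lt(abs(dp$p_correct - cf$p_correct), 1e-10)
    expect_lt(abs(dp$expected_time - cf$expected_time), 1e-10)
    expect_lt(dp$unabsorbed_mass, 1e-10)
  }
})

test_that("closed form refuses non-lattice walks and points to the DP solver", {
  # asymmetric steps
  expect_error(
    ruin_closed_form(walk_spec(0.7, log(7 / 4), log(3 / 6), log(4))),
    class = "sprteffort_not_lattice"
  )
  # symmetric but boundary not an integer multiple of the step
  expect_error(
    ruin_closed_form(walk_spec(0.75, log(3), -log(3), 1.5 * log(3))),
    class = "sprteffort_not_lattice"
  )
})

test_that("probability mass is conserved through absorption", {
  set.seed(8)
  for (i in 1:10) {
    w <- walk_spec(
      p_up = runif(1, 0.5, 0.9),
      w_plus = runif(1, 0.1, 1),
      w_minus = -runif(1, 0.1, 1),
      threshold = runif(1, 0.5, 3)
    )
    dp <- dp_absorption(w, t_max = 2000)
    expect_lt(abs(dp$p_correct + dp$p_wrong + dp$unabsorbed_mass - 1), 1e-12)
  }
})

test_that("DP oracle agrees with simulation on an asymmetric environment", {
  # near-perfect perception of an asymmetric world: eps' ~ (0.7, 0.4)
  env <- sprt_environment(eps_good = 0.7, eps_bad = 0.4)
  pol <- sprt_policy(theta = 0.8, phi = 1 - 1e-12)
  ora <- oracle_summary(env, pol, t_max = 500)
  expect_true(ora$valid)
  n <- 2e5
  sim <- simulate_ensemble(env, pol, n_trials = n, seed = 55, t_max = 500)
  expect_equal(sim$n_truncated, 0L)
  expect_lt(
    abs(sim$p_correct - ora$p_correct),
    3 * binom_se(ora$p_correct, n)
  )
  expect_lte(
    abs(sim$mean_dt - ora$mean_dt),
    3 * oracle_dt_sd(env, pol, t_max = 500) / sqrt(n) + 1e-9
  )
})

test_that("a vanishing threshold forces a one-sample decision", {
  env <- default_env()
  pol <- sprt_policy(theta = 0.5005, phi = 0.8) # threshold 0.002 << step
  s <- oracle_summary(env, pol)
  expect_equal(s$mean_dt, 1)
  # single-sample accuracy is the effective read-1 probability under good
  expect_equal(s$p_correct, adjusted_params(0.8, env)$eps_good_eff)
})

test_that("prior-weighted DP reproduces the accuracy used in fitness evaluation", {
  # asymmetric case where good and bad states genuinely differ
  env <- sprt_environment(eps_good = 0.8, eps_bad = 0.45)
  pol <- sprt_policy(theta = 0.85, phi = 0.9)
  good <- dp_absorption(as_walk(env, pol, "good"), 2000)
  bad <- dp_absorption(as_walk(env, pol, "bad"), 2000)
  s <- oracle_summary(env, pol, t_max = 2000)
  decided <- 1 - (0.5 * good$unabsorbed_mass + 0.5 * bad$unabsorbed_mass)
  expect_equal(
    s$p_correct,
    (0.5 * good$p_correct + 0.5 * bad$p_correct) / decided
  )
  expect_equal(
    s$mean_dt,
    0.5 * good$expected_time + 0.5 * bad$expected_time
  )
})
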