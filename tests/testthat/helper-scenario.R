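# Shared builders for the default study scenario and small test grids.

default_env <- function(c_time = 0.02) {
  sprt_environment(
    eps_good = 0.75, eps_bad = 0.25, prior_good = 0.5,
    benefit = 10, c_time = c_time
  )
}

default_costs <- function() cost_model(k = 0.05)

# Small oracle-mode grid that still contains the default scenario's
# baseline optimum region.
small_grid <- function(mode = "oracle", n_trials = 1000L, seed = 1L,
                       t_max = 10000L) {
  grid_spec(
    theta = seq(0.6, 0.95, by = 0.05),
    phi = seq(0.3, 0.9, by = 0.1),
    n_trials = n_trials, t_max = t_max, seed = seed, mode = mode
  )
}

# Build a landscape object directly from synthetic per-cell fitness, for
# tests of the argmax and peak-count logic that need exact surfaces.
synthetic_landscape <- function(theta, phi, fitness_fun) {
  grid <- grid_spec(theta = theta, phi = phi)
  cells <- tidyr::expand_grid(theta = theta, phi = phi)
  cells$p_correct <- 0.8
  cells$mean_dt <- 2
  cells$c_effort <- cost_from_phi(cells$phi, 0.05)
  cells$fitness <- fitness_fun(cells$theta, cells$phi)
  cells$valid <- TRUE
  cells <- cells[, c("theta", "phi", "p_correct", "mean_dt", "c_effort",
                     "fitness", "valid")]
  sprteffort:::new_landscape(cells, default_env(), default_costs(), grid)
}

# Binomial standard error for a proportion.
binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# Standard deviation of the absorption time of a policy, from the exact
# second moment of the oracle walk (prior-weighted over true states).
oracle_dt_sd <- function(env, policy, t_max = 10000L) {
  good <- dp_absorption(as_walk(env, policy, "good"), t_max)
  bad <- dp_absorption(as_walk(env, policy, "bad"), t_max)
  pg <- env$prior_good
  m1 <- pg * good$expected_time + (1 - pg) * bad$expected_time
  m2 <- pg * good$expected_time_sq + (1 - pg) * bad$expected_time_sq
  sqrt(max(m2 - m1^2, 0)) # deterministic times can round a hair negative
}
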