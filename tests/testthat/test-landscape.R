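test_that("fitness is benefit times accuracy minus total time cost", {
  expect_equal(fitness_value(1, 1, benefit = 10, c_time = 1, c_effort = 1), 8)
  expect_equal(
    fitness_value(0.9, 3.2, benefit = 10, c_time = 0.5, c_effort = 0.5),
    5.8
  )
  # without benefit, fitness is pure cost
  expect_true(all(
    fitness_value(c(0, 0.5, 1), c(1, 5, 20), 0, 0.1, 0.2) <= 0
  ))
})

test_that("a single-cell landscape is one ensemble summary plus fitness", {
  env <- default_env()
  costs <- default_costs()
  grid <- grid_spec(
    theta = 0.8, phi = 0.6, n_trials = 500, seed = 17, mode = "simulate"
  )
  land <- evaluate_landscape(env, costs, grid)
  expect_equal(nrow(land), 1L)
  ens <- simulate_ensemble(
    env, sprt_policy(0.8, 0.6),
    n_trials = 500, seed = sprteffort:::cell_seed(17, 1, 1)
  )
  expect_equal(land$p_correct, ens$p_correct)
  expect_equal(land$mean_dt, ens$mean_dt)
  expect_equal(
    land$fitness,
    fitness_value(ens$p_correct, ens$mean_dt, env$benefit, env$c_time,
                  cost_from_phi(0.6, costs$k))
  )
})

test_that("simulated landscapes agree with the oracle cell-wise", {
  env <- default_env()
  costs <- default_costs()
  thetas <- seq(0.65, 0.85, by = 0.05)
  phis <- seq(0.5, 0.9, by = 0.1)
  n <- 1e4
  sim <- evaluate_landscape(
    env, costs,
    grid_spec(theta = thetas, phi = phis, n_trials = n, seed = 4,
              mode = "simulate")
  )
  ora <- evaluate_landscape(
    env, costs,
    grid_spec(theta = thetas, phi = phis, mode = "oracle")
  )
  for (r in seq_len(nrow(sim))) {
    pol <- sprt_policy(sim$theta[r], sim$phi[r])
    expect_lt(
      abs(sim$p_correct[r] - ora$p_correct[r]),
      3 * binom_se(ora$p_correct[r], n)
    )
    expect_lte(
      abs(sim$mean_dt[r] - ora$mean_dt[r]),
      3 * oracle_dt_sd(env, pol) / sqrt(n) + 1e-9
    )
  }
})

test_that("landscapes are reproducible from the master seed", {
  env <- default_env()
  grid <- grid_spec(
    theta = c(0.7, 0.8), phi = c(0.5, 0.7), n_trials = 300, seed = 99,
    mode = "simulate"
  )
  a <- evaluate_landscape(env, default_costs(), grid)
  b <- evaluate_landscape(env, default_costs(), grid)
  expect_identical(tidy(a), tidy(b))
})

test_that("the optimum is the argmax over valid cells, ties to smallest theta then phi", {
  env <- default_env()
  land <- evaluate_landscape(env, default_costs(), small_grid())
  opt <- find_optimum(land)
  # brute-force scan, written independently of find_optimum
  best <- NULL
  cells <- tidy(land)
  for (r in seq_len(nrow(cells))) {
    if (!cells$valid[r]) next
    if (is.null(best) || cells$fitness[r] > best$fitness) best <- cells[r, ]
  }
  expect_equal(opt$fitness, best$fitness)
  expect_equal(opt$theta, best$theta)

  # exact tie between two cells: lexicographically smaller wins
  tied <- synthetic_landscape(
    c(0.6, 0.7, 0.8), c(0.2, 0.4),
    function(theta, phi) ifelse(theta >= 0.7 & phi == 0.4, 5, 1)
  )
  expect_message(opt2 <- find_optimum(tied), "tie")
  expect_equal(opt2$theta, 0.7)
  expect_equal(opt2$phi, 0.4)
})

test_that("truncating cells are flagged invalid, and all-invalid landscapes error", {
  env <- default_env()
  # phi = 0 never terminates: the cell must be invalid, not averaged in
  land <- evaluate_landscape(
    env, default_costs(),
    grid_spec(theta = c(0.7, 0.8), phi = c(0, 0.6), n_trials = 100,
              t_max = 200, seed = 2, mode = "simulate")
  )
  expect_true(all(!land$valid[land$phi == 0]))
  expect_true(all(land$valid[land$phi == 0.6]))
  expect_error(
    evaluate_landscape(
      env, default_costs(),
      grid_spec(theta = 0.8, phi = 0, n_trials = 50, t_max = 100,
                seed = 2, mode = "simulate")
    ),
    "invalid"
  )
})

test_that("peak counting distinguishes concave surfaces from multi-modal ones", {
  thetas <- seq(0.6, 0.9, by = 0.05)
  phis <- seq(0.1, 0.9, by = 0.1)
  concave <- synthetic_landscape(
    thetas, phis,
    function(theta, phi) -(theta - 0.75)^2 - (phi - 0.5)^2
  )
  expect_true(is_single_peaked(concave))
  expect_equal(attr(is_single_peaked(concave), "n_peaks"), 1L)

  bimodal <- synthetic_landscape(
    thetas, phis,
    function(theta, phi) {
      -pmin((theta - 0.65)^2 + (phi - 0.3)^2,
            (theta - 0.85)^2 + (phi - 0.7)^2)
    }
  )
  res <- is_single_peaked(bimodal)
  expect_false(res)
  expect_equal(attr(res, "n_peaks"), 2L)
})

test_that("landscape round-trips through its tab-delimited export", {
  env <- default_env()
  land <- evaluate_landscape(
    env, default_costs(),
    grid_spec(theta = c(0.7, 0.8), phi = c(0.4, 0.6))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(land, path)
  lines <- readLines(path)
  expect_equal(
    lines[1],
    "theta\tphi\tp_correct\tmean_dt\tc_effort\tfitness\tvalid"
  )
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tidy(land)))
})
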