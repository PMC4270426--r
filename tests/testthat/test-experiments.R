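test_that("relative fitness advantage is a signed, zero-anchored ratio", {
  expect_equal(relative_fitness_advantage(6, 5)$advantage, 0.2)
  expect_equal(relative_fitness_advantage(5, 5)$advantage, 0)
  expect_equal(relative_fitness_advantage(4, 5)$advantage, -0.2)
  expect_equal(relative_fitness_advantage(6, 5)$difference, 1)
  # sign convention survives a negative reference
  expect_equal(relative_fitness_advantage(-1, -2)$advantage, 0.5)
  # degenerate reference: advantage undefined, difference still reported
  expect_warning(
    res <- relative_fitness_advantage(3, 0),
    class = "sprteffort_zero_reference"
  )
  expect_true(is.na(res$advantage))
  expect_equal(res$difference, 3)
})

test_that("both agent types select the same cell under the baseline regime", {
  env <- default_env()
  cmp <- compare_across_time_costs(
    env, default_costs(), small_grid(),
    c_time_values = 0.02
  )
  t1 <- cmp[cmp$agent_type == "type1", ]
  t2 <- cmp[cmp$agent_type == "type2", ]
  expect_identical(t1$theta_opt, t2$theta_opt)
  expect_identical(t1$phi_used, t2$phi_used)
  expect_identical(t1$fitness, t2$fitness)
  expect_identical(t1$rel_advantage, 0)
})

test_that("type 2 never beats type 1 and loses strictly off-baseline", {
  env <- default_env()
  cmp <- compare_across_time_costs(
    env, default_costs(), small_grid(),
    c_time_values = c(0.002, 0.02, 0.2)
  )
  wide <- tidyr::pivot_wider(
    tidy(cmp)[, c("c_time", "agent_type", "fitness", "p_correct")],
    names_from = "agent_type", values_from = c("fitness", "p_correct")
  )
  expect_true(all(wide$fitness_type1 >= wide$fitness_type2))
  off <- wide[abs(wide$c_time - 0.02) > 1e-12, ]
  expect_true(any(off$fitness_type1 > off$fitness_type2 + 1e-9))
})

test_that("a one-column effort grid makes the two types identical everywhere", {
  env <- default_env()
  grid <- grid_spec(theta = seq(0.6, 0.9, by = 0.05), phi = 0.6)
  cmp <- compare_across_time_costs(
    env, default_costs(), grid,
    c_time_values = c(0.01, 0.02, 0.08)
  )
  t1 <- cmp[cmp$agent_type == "type1", ]
  t2 <- cmp[cmp$agent_type == "type2", ]
  expect_equal(t1$fitness, t2$fitness)
  expect_true(all(t1$rel_advantage == 0))
})

test_that("single-cost optimisers agree with the landscape optimum", {
  env <- default_env()
  costs <- default_costs()
  grid <- small_grid()
  land <- evaluate_landscape(env, costs, grid)
  opt <- find_optimum(land)
  t1 <- optimize_type1(env, costs, grid, c_time = env$c_time)
  expect_equal(t1$theta_opt, opt$theta)
  expect_equal(t1$phi_used, opt$phi)
  expect_equal(t1$fitness, opt$fitness)
  # fixing phi at the 2-D optimum cannot change the answer
  t2 <- optimize_type2(env, costs, grid, c_time = env$c_time,
                       phi_fixed = opt$phi)
  expect_equal(t2$fitness, t1$fitness)
  expect_error(
    optimize_type2(env, costs, grid, phi_fixed = 0.123),
    "phi grid"
  )
})

test_that("optimal agents substitute effort for time as time grows dear", {
  env <- default_env()
  sub <- substitution_curve(
    env, default_costs(), small_grid(),
    c_time_values = c(0.002, 0.2) # a factor of 100 apart
  )
  expect_lte(sub$mean_dt_opt[2], sub$mean_dt_opt[1])
  expect_gte(sub$c_effort_opt[2], sub$c_effort_opt[1])
  expect_equal(
    sub$total_effort_spend,
    sub$c_effort_opt * sub$mean_dt_opt
  )
})

test_that("substitution ordering is stable under grid refinement", {
  env <- default_env()
  costs <- default_costs()
  cts <- log_spaced(0.002, 0.2, 6)
  coarse <- substitution_curve(
    env, costs,
    grid_spec(theta = seq(0.6, 0.95, by = 0.05), phi = seq(0.3, 0.9, by = 0.1)),
    c_time_values = cts
  )
  fine <- substitution_curve(
    env, costs,
    grid_spec(theta = seq(0.6, 0.95, by = 0.025), phi = seq(0.3, 0.9, by = 0.05)),
    c_time_values = cts
  )
  for (s in list(coarse, fine)) {
    expect_true(all(diff(s$mean_dt_opt) <= 1e-9))
    expect_true(all(diff(s$c_effort_opt) >= -1e-9))
  }
})

test_that("comparison and substitution tables export as tab-delimited text", {
  env <- default_env()
  cmp <- compare_across_time_costs(
    env, default_costs(), small_grid(), c_time_values = c(0.01, 0.02)
  )
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(cmp, p1)
  expect_equal(strsplit(readLines(p1)[1], "\t")[[1]][1:4],
               c("c_time", "agent_type", "theta_opt", "phi_used"))
  sub <- substitution_curve(
    env, default_costs(), small_grid(), c_time_values = c(0.01, 0.1)
  )
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_substitution(sub, p2)
  expect_equal(length(readLines(p2)), 3L) # header + 2 costs
})
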