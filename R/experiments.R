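#' Relative fitness advantage of one strategy over another
#'
#' Defined as `(w1 - w2) / abs(w2)`: zero when the two fitnesses are
#' equal, positive when the first strategy does better. The absolute
#' difference `w1 - w2` is always returned alongside; when the reference
#' fitness is within `tol` of zero the ratio is undefined and returned as
#' `NA` with a warning of class `sprteffort_zero_reference`.
#'
#' @param w1 Fitness of the focal (flexible) strategy.
#' @param w2 Fitness of the reference strategy.
#' @param tol Magnitude below which `w2` is treated as zero.
#' @return A tibble with columns `advantage` and `difference`, one row
#'   per input pair.
#' @examples
#' relative_fitness_advantage(6, 5)  # advantage 0.2
#' @export
relative_fitness_advantage <- function(w1, w2, tol = 1e-12) {
  stopifnot(is.numeric(w1), is.numeric(w2), length(w1) == length(w2))
  degenerate <- abs(w2) <= tol
  if (any(degenerate)) {
    warn(
      "Reference fitness is (numerically) zero; relative advantage is undefined and returned as NA.",
      class = "sprteffort_zero_reference"
    )
  }
  advantage <- ifelse(degenerate, NA_real_, (w1 - w2) / abs(w2))
  tibble(advantage = advantage, difference = w1 - w2)
}

# Optimal cell of a precomputed dynamics table for a given time cost,
# optionally restricted to one effort column. Shared by both agent types
# so dominance and baseline identity hold exactly.
optimum_at_cost <- function(dyn, env, costs, c_time, phi_fixed = NULL) {
  cells <- dyn |>
    mutate(
      c_effort = cost_from_phi(.data$phi, costs$k),
      fitness = fitness_value(
        .data$p_correct, .data$mean_dt, env$benefit, c_time, .data$c_effort
      )
    )
  if (!is.null(phi_fixed)) {
    cells <- cells[abs(cells$phi - phi_fixed) < 1e-9, ]
    if (nrow(cells) == 0L) {
      abort("`phi_fixed` is not a value of the phi grid.")
    }
  }
  valid <- cells[cells$valid & is.finite(cells$fitness), ]
  if (nrow(valid) == 0L) abort("No valid cells at this time cost.")
  top <- valid[valid$fitness == max(valid$fitness), ]
  top <- top[order(top$theta, top$phi), ]
  top[1L, ]
}

comparison_record <- function(cell, c_time, agent_type) {
  tibble(
    c_time = c_time,
    agent_type = agent_type,
    theta_opt = cell$theta,
    phi_used = cell$phi,
    p_correct = cell$p_correct,
    mean_dt = cell$mean_dt,
    c_effort = cell$c_effort,
    fitness = cell$fitness
  )
}

#' Optimal strategy for a fully flexible (Type 1) agent
#'
#' A Type 1 agent adapts both its threshold parameter and its effort
#' level to the prevailing cost of time: its optimum is the full
#' two-dimensional argmax over the policy grid.
#'
#' @param env An [sprt_environment()] (its `c_time` is overridden by the
#'   `c_time` argument for the purposes of this record).
#' @param costs A [cost_model()].
#' @param grid A [grid_spec()].
#' @param c_time Baseline time cost at which to optimise.
#' @return A one-row tibble: `c_time`, `agent_type`, `theta_opt`,
#'   `phi_used`, `p_correct`, `mean_dt`, `c_effort`, `fitness`.
#' @export
optimize_type1 <- function(env, costs, grid, c_time = env$c_time) {
  dyn <- landscape_dynamics(env, costs, grid)
  comparison_record(
    optimum_at_cost(dyn, env, costs, c_time), c_time, "type1"
  )
}

#' Optimal strategy for a fixed-effort (Type 2) agent
#'
#' A Type 2 agent's effort level is frozen (at the optimum of the
#' baseline regime it evolved under); only the threshold parameter is
#' optimised, over the single effort column `phi_fixed` of the grid.
#'
#' @inheritParams optimize_type1
#' @param phi_fixed The frozen effort level; must be a value of the phi
#'   grid (in the intended use, the baseline Type 1 optimum).
#' @return A one-row tibble, as [optimize_type1()].
#' @export
optimize_type2 <- function(env, costs, grid, c_time = env$c_time,
                           phi_fixed) {
  dyn <- landscape_dynamics(env, costs, grid)
  comparison_record(
    optimum_at_cost(dyn, env, costs, c_time, phi_fixed = phi_fixed),
    c_time, "type2"
  )
}

#' Compare flexible and fixed-effort agents across time costs
#'
#' For each time cost, finds the Type 1 optimum (free theta and phi) and
#' the Type 2 optimum (theta only, phi frozen at the *baseline* Type 1
#' optimum) on one shared performance table, so that the dominance
#' `W(type1) >= W(type2)` and the baseline identity (identical records at
#' the baseline cost, relative advantage exactly zero) hold exactly
#' rather than up to simulation noise.
#'
#' @param env An [sprt_environment()].
#' @param costs A [cost_model()].
#' @param grid A [grid_spec()].
#' @param c_time_values Time costs to sweep; must include `baseline`.
#' @param baseline The baseline time cost that Type 2's effort level is
#'   adapted to. Defaults to `env$c_time`.
#' @return A tibble of class `sprt_comparison`: two rows (one per agent
#'   type) per time cost, with the per-cost relative fitness advantage of
#'   Type 1 over Type 2 in `rel_advantage` and the absolute fitness
#'   difference in `fitness_diff`.
#' @examples
#' \donttest{
#' env <- sprt_environment()
#' cmp <- compare_across_time_costs(
#'   env, cost_model(0.05), grid_spec(),
#'   c_time_values = c(0.01, 0.02, 0.04)
#' )
#' }
#' @export
compare_across_time_costs <- function(env, costs, grid,
                                      c_time_values,
                                      baseline = env$c_time) {
  stopifnot(is.numeric(c_time_values), length(c_time_values) >= 1)
  if (!any(abs(c_time_values - baseline) < 1e-12)) {
    abort("`c_time_values` must include the baseline time cost.")
  }
  dyn <- landscape_dynamics(env, costs, grid)
  base_opt <- optimum_at_cost(dyn, env, costs, baseline)
  phi_fixed <- base_opt$phi
  records <- purrr::map_dfr(c_time_values, function(ct) {
    t1 <- optimum_at_cost(dyn, env, costs, ct)
    t2 <- optimum_at_cost(dyn, env, costs, ct, phi_fixed = phi_fixed)
    adv <- relative_fitness_advantage(t1$fitness, t2$fitness)
    bind_rows(
      comparison_record(t1, ct, "type1"),
      comparison_record(t2, ct, "type2")
    ) |>
      mutate(rel_advantage = adv$advantage, fitness_diff = adv$difference)
  })
  structure(
    records,
    class = c("sprt_comparison", class(tibble())),
    env = env, costs = costs, grid = grid,
    baseline = baseline, phi_fixed = phi_fixed
  )
}

#' Optimal time and effort expenditure across time costs
#'
#' Traces the Type 1 optimum as the baseline cost of time sweeps across a
#' range (canonically two orders of magnitude, log-spaced): the mean
#' decision time at the optimum, the effort cost paid per sample, and the
#' total effort expenditure per decision. Where time is expensive an
#' optimal decision-maker spends more on effort per-unit-time and less on
#' time; the curve makes that substitution explicit.
#'
#' @inheritParams compare_across_time_costs
#' @param c_time_values Time costs to sweep (need not include a
#'   baseline). Default: 20 log-spaced values over `[0.002, 0.2]`.
#' @return A tibble of class `sprt_substitution` with columns `c_time`,
#'   `theta_opt`, `phi_opt`, `p_correct_opt`, `mean_dt_opt`,
#'   `c_effort_opt`, `total_effort_spend` (`c_effort_opt * mean_dt_opt`)
#'   and `fitness`.
#' @export
substitution_curve <- function(env, costs, grid,
                               c_time_values = log_spaced(0.002, 0.2, 20)) {
  stopifnot(is.numeric(c_time_values), length(c_time_values) >= 1)
  dyn <- landscape_dynamics(env, costs, grid)
  out <- purrr::map_dfr(c_time_values, function(ct) {
    cell <- optimum_at_cost(dyn, env, costs, ct)
    tibble(
      c_time = ct,
      theta_opt = cell$theta,
      phi_opt = cell$phi,
      p_correct_opt = cell$p_correct,
      mean_dt_opt = cell$mean_dt,
      c_effort_opt = cell$c_effort,
      total_effort_spend = cell$c_effort * cell$mean_dt,
      fitness = cell$fitness
    )
  })
  structure(
    out,
    class = c("sprt_substitution", class(tibble())),
    env = env, costs = costs, grid = grid
  )
}

#' Log-spaced sequence
#'
#' @param from,to Positive endpoints.
#' @param n Number of points.
#' @return Numeric vector of `n` values, geometrically spaced.
#' @export
log_spaced <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 1)
  exp(seq(log(from), log(to), length.out = n))
}

#' @rdname compare_across_time_costs
#' @param x An `sprt_comparison`.
#' @param ... Unused.
#' @export
tidy.sprt_comparison <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  for (a in c("env", "costs", "grid", "baseline", "phi_fixed")) {
    attr(out, a) <- NULL
  }
  out
}

#' @rdname compare_across_time_costs
#' @export
glance.sprt_comparison <- function(x, ...) {
  adv <- x$rel_advantage[x$agent_type == "type1"]
  tibble(
    baseline = attr(x, "baseline"),
    phi_fixed = attr(x, "phi_fixed"),
    n_costs = length(unique(x$c_time)),
    max_rel_advantage = max(adv),
    dominance_holds = all(x$fitness_diff >= -1e-12)
  )
}

#' @rdname substitution_curve
#' @param x An `sprt_substitution`.
#' @param ... Unused.
#' @export
tidy.sprt_substitution <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  for (a in c("env", "costs", "grid")) attr(out, a) <- NULL
  out
}

#' @rdname substitution_curve
#' @export
glance.sprt_substitution <- function(x, ...) {
  tibble(
    n_costs = nrow(x),
    dt_non_increasing = all(diff(x$mean_dt_opt) <= 1e-9),
    c_effort_non_decreasing = all(diff(x$c_effort_opt) >= -1e-9),
    dt_range = max(x$mean_dt_opt) - min(x$mean_dt_opt)
  )
}

#' Plot an agent-type comparison
#'
#' @param object An `sprt_comparison`.
#' @param ... Unused.
#' @return A ggplot: accuracy, decision time and fitness by time cost and
#'   agent type.
#' @export
autoplot.sprt_comparison <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(
      c("p_correct", "mean_dt", "fitness"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(factor(.data$c_time), .data$value, fill = .data$agent_type)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "cost of time per sample", y = NULL, fill = NULL,
      title = "Flexible (type 1) vs fixed-effort (type 2) decision-makers"
    )
}

#' Plot a substitution curve
#'
#' @param object An `sprt_substitution`.
#' @param ... Unused.
#' @return A ggplot: optimal decision time and per-sample effort spend
#'   against the cost of time (log scale).
#' @export
autoplot.sprt_substitution <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(
      c("mean_dt_opt", "c_effort_opt"),
      names_to = "quantity", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$c_time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "cost of time per sample (log scale)", y = NULL,
      title = "Substitution of effort per-unit-time for time"
    )
}

#' Write comparison and substitution tables as tab-delimited text
#'
#' @param x An `sprt_comparison` or `sprt_substitution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "sprt_comparison"))
  readr::write_tsv(tidy(x), path)
  invisible(path)
}

#' @rdname write_comparison
#' @export
write_substitution <- function(x, path) {
  stopifnot(inherits(x, "sprt_substitution"))
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
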