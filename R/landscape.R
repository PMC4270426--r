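#' Specify a discrete policy grid
#'
#' The optimal strategy search is a grid search: decision performance is
#' evaluated for every pair of threshold and effort values, either by
#' stochastic simulation (`mode = "simulate"`, mirroring the original
#' procedure) or exactly via the absorption oracles (`mode = "oracle"`,
#' the default, which removes sampling noise from the optimisation).
#'
#' @param theta Strictly increasing vector of threshold values in
#'   (0.5, 1). Default: 0.55 to 0.99 in steps of 0.01.
#' @param phi Strictly increasing vector of effort levels in `[0, 0.98]`.
#'   Default: 0 to 0.98 in steps of 0.02; 1 is excluded because its
#'   effort cost diverges.
#' @param n_trials Ensemble size per cell in simulate mode.
#' @param t_max Truncation cap per trial (and step cap for the oracle).
#' @param seed Master seed; per-cell seeds are derived deterministically
#'   from `(seed, theta index, phi index)` so cells are independent and
#'   the landscape is reproducible.
#' @param mode `"oracle"` or `"simulate"`.
#' @return An object of class `sprt_grid`.
#' @export
grid_spec <- function(theta = seq(0.55, 0.99, by = 0.01),
                      phi = seq(0, 0.98, by = 0.02),
                      n_trials = 10000L, t_max = 10000L, seed = 1L,
                      mode = c("oracle", "simulate")) {
  mode <- match.arg(mode)
  check_theta(theta)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 0.98)) {
    abort("`phi` grid values must lie in [0, 0.98].")
  }
  if (length(theta) > 1 && any(diff(theta) <= 0)) {
    abort("`theta` grid must be strictly increasing.")
  }
  if (length(phi) > 1 && any(diff(phi) <= 0)) {
    abort("`phi` grid must be strictly increasing.")
  }
  stopifnot(n_trials >= 1, t_max >= 1)
  structure(
    list(
      theta = theta, phi = phi, n_trials = as.integer(n_trials),
      t_max = as.integer(t_max), seed = as.integer(seed), mode = mode
    ),
    class = "sprt_grid"
  )
}

#' Absolute fitness of a decision strategy
#'
#' Fitness is the expected benefit of deciding correctly minus the total
#' expected cost of the decision:
#' `W = benefit * p_correct - (c_time + c_effort) * mean_dt`.
#'
#' @param p_correct Proportion of correct decisions.
#' @param mean_dt Mean decision time, in samples.
#' @param benefit Benefit of a correct decision.
#' @param c_time Baseline cost per sample.
#' @param c_effort Effort cost per sample.
#' @return Fitness, in the same units as `benefit`. Vectorised.
#' @examples
#' fitness_value(0.9, 3.2, benefit = 10, c_time = 0.5, c_effort = 0.5)
#' @export
fitness_value <- function(p_correct, mean_dt, benefit, c_time, c_effort) {
  benefit * p_correct - (c_time + c_effort) * mean_dt
}

# Decision performance (p_correct, mean_dt, valid) over the grid. The
# true-state dynamics do not depend on c_time, so callers can reuse this
# table across time costs and recompute only the fitness column.
landscape_dynamics <- function(env, costs, grid) {
  stopifnot(
    inherits(env, "sprt_environment"), inherits(costs, "sprt_costs"),
    inherits(grid, "sprt_grid")
  )
  cells <- tidyr::expand_grid(
    i_theta = seq_along(grid$theta),
    i_phi = seq_along(grid$phi)
  )
  cells$theta <- grid$theta[cells$i_theta]
  cells$phi <- grid$phi[cells$i_phi]
  one_cell <- if (grid$mode == "oracle") {
    function(i_theta, i_phi, theta, phi) {
      s <- oracle_summary(env, sprt_policy(theta, phi), t_max = grid$t_max)
      tibble(p_correct = s$p_correct, mean_dt = s$mean_dt, valid = s$valid)
    }
  } else {
    function(i_theta, i_phi, theta, phi) {
      s <- simulate_ensemble(
        env, sprt_policy(theta, phi),
        n_trials = grid$n_trials,
        seed = cell_seed(grid$seed, i_theta, i_phi),
        t_max = grid$t_max
      )
      tibble(
        p_correct = s$p_correct, mean_dt = s$mean_dt,
        valid = s$n_truncated == 0L
      )
    }
  }
  perf <- purrr::pmap(cells, one_cell)
  dplyr::bind_cols(
    cells[c("theta", "phi")],
    dplyr::bind_rows(perf)
  )
}

#' Evaluate a fitness landscape over a policy grid
#'
#' Computes decision accuracy, mean decision time and fitness for every
#' (theta, phi) cell of the grid. Cells whose trials truncate (simulate
#' mode) or whose walk cannot absorb within the step cap (oracle mode;
#' in particular the uninformative `phi = 0` column) are marked invalid
#' and never averaged into the optimum.
#'
#' @param env An [sprt_environment()]; its `c_time` and `benefit` enter
#'   the fitness of every cell.
#' @param costs A [cost_model()].
#' @param grid A [grid_spec()].
#' @return A tibble of class `sprt_landscape` with one row per cell and
#'   columns `theta`, `phi`, `p_correct`, `mean_dt`, `c_effort`,
#'   `fitness`, `valid`. The environment, cost model, grid and optimum
#'   are attached as attributes.
#' @examples
#' env <- sprt_environment()
#' land <- evaluate_landscape(env, cost_model(0.05),
#'   grid_spec(theta = seq(0.6, 0.9, 0.1), phi = c(0.3, 0.6, 0.9)))
#' find_optimum(land)
#' @export
evaluate_landscape <- function(env, costs, grid) {
  dyn <- landscape_dynamics(env, costs, grid)
  cells <- dyn |>
    mutate(
      c_effort = cost_from_phi(.data$phi, costs$k),
      fitness = fitness_value(
        .data$p_correct, .data$mean_dt, env$benefit, env$c_time,
        .data$c_effort
      )
    ) |>
    dplyr::select(
      "theta", "phi", "p_correct", "mean_dt", "c_effort", "fitness", "valid"
    )
  if (!any(cells$valid)) {
    abort("All landscape cells are invalid (no decision ever terminates).")
  }
  out <- new_landscape(cells, env, costs, grid)
  attr(out, "optimum") <- find_optimum(out)
  out
}

new_landscape <- function(cells, env, costs, grid) {
  structure(
    cells,
    class = c("sprt_landscape", class(tibble())),
    env = env, costs = costs, grid = grid
  )
}

#' Locate the optimal strategy on a landscape
#'
#' Returns the valid cell with the greatest fitness. Exact ties (which
#' arise naturally in oracle mode, where fitness is piecewise constant in
#' theta for symmetric environments) are broken lexicographically --
#' smallest theta, then smallest phi -- and the tie is reported via a
#' message.
#'
#' @param landscape An `sprt_landscape`.
#' @return A one-row tibble: the optimal cell.
#' @export
find_optimum <- function(landscape) {
  stopifnot(inherits(landscape, "sprt_landscape"))
  cells <- as_tibble(landscape)
  valid <- cells[cells$valid & is.finite(cells$fitness), ]
  if (nrow(valid) == 0L) abort("Landscape has no valid cells.")
  top <- valid[valid$fitness == max(valid$fitness), ]
  if (nrow(top) > 1L) {
    rlang::inform(sprintf(
      "find_optimum: %d cells tie at the maximum fitness; taking smallest theta, then smallest phi.",
      nrow(top)
    ))
  }
  top <- top[order(top$theta, top$phi), ]
  top[1L, ]
}

#' Count local maxima of a fitness landscape
#'
#' A local maximum is a plateau (a connected component of equal-fitness
#' valid cells under the 4-neighbourhood on the grid, equality within
#' `tol`) none of whose members has a strictly fitter valid neighbour.
#' Invalid cells are excluded from the comparison.
#'
#' @param landscape An `sprt_landscape` covering a full rectangular grid.
#' @param tol Absolute tolerance for treating two cells as tied.
#' @return `TRUE` if the landscape has exactly one local maximum. The
#'   number of maxima and the cells of each peak are attached as
#'   attributes `n_peaks` and `peaks`.
#' @export
is_single_peaked <- function(landscape, tol = 1e-9) {
  stopifnot(inherits(landscape, "sprt_landscape"))
  grid <- attr(landscape, "grid")
  cells <- as_tibble(landscape)
  nt <- length(grid$theta)
  np <- length(grid$phi)
  stopifnot(nrow(cells) == nt * np)
  # cells are in expand_grid order: phi varies fastest within theta
  w <- matrix(cells$fitness, nrow = np, ncol = nt)
  valid <- matrix(cells$valid & is.finite(cells$fitness), nrow = np, ncol = nt)
  w[!valid] <- NA_real_
  comp <- matrix(0L, np, nt)
  n_comp <- 0L
  offsets <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  neighbours <- function(i, j) {
    out <- list()
    for (d in offsets) {
      ii <- i + d[1L]
      jj <- j + d[2L]
      if (ii >= 1L && ii <= np && jj >= 1L && jj <= nt && valid[ii, jj]) {
        out[[length(out) + 1L]] <- c(ii, jj)
      }
    }
    out
  }
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      if (!valid[i, j] || comp[i, j] > 0L) next
      n_comp <- n_comp + 1L
      stack <- list(c(i, j))
      comp[i, j] <- n_comp
      while (length(stack) > 0L) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (q in neighbours(cur[1L], cur[2L])) {
          if (comp[q[1L], q[2L]] == 0L &&
              abs(w[q[1L], q[2L]] - w[cur[1L], cur[2L]]) <= tol) {
            comp[q[1L], q[2L]] <- n_comp
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  is_max <- rep(TRUE, n_comp)
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      if (!valid[i, j]) next
      for (q in neighbours(i, j)) {
        if (w[q[1L], q[2L]] > w[i, j] + tol) is_max[comp[i, j]] <- FALSE
      }
    }
  }
  peak_ids <- which(is_max)
  peaks <- purrr::map_dfr(peak_ids, function(id) {
    idx <- which(comp == id, arr.ind = TRUE)
    tibble(
      peak = id,
      theta = grid$theta[idx[, "col"]],
      phi = grid$phi[idx[, "row"]],
      fitness = w[idx]
    )
  })
  out <- length(peak_ids) == 1L
  attr(out, "n_peaks") <- length(peak_ids)
  attr(out, "peaks") <- peaks
  out
}

#' @export
print.sprt_landscape <- function(x, ...) {
  opt <- attr(x, "optimum")
  cat(sprintf(
    "<sprt_landscape> %d cells (%d valid), mode = %s\n",
    nrow(x), sum(x$valid), attr(x, "grid")$mode
  ))
  if (!is.null(opt)) {
    cat(sprintf(
      "  optimum: theta* = %g, phi* = %g, fitness = %.4f\n",
      opt$theta, opt$phi, opt$fitness
    ))
  }
  NextMethod()
}

#' Tidiers for fitness landscapes
#'
#' `tidy()` returns the per-cell table; `glance()` returns a one-row
#' summary with the optimum and grid diagnostics.
#'
#' @param x An `sprt_landscape`.
#' @param ... Unused.
#' @export
tidy.sprt_landscape <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "env") <- NULL
  attr(out, "costs") <- NULL
  attr(out, "grid") <- NULL
  attr(out, "optimum") <- NULL
  out
}

#' @rdname tidy.sprt_landscape
#' @export
glance.sprt_landscape <- function(x, ...) {
  opt <- find_optimum(x)
  tibble(
    n_cells = nrow(x),
    n_valid = sum(x$valid),
    theta_opt = opt$theta,
    phi_opt = opt$phi,
    fitness_max = opt$fitness,
    p_correct_opt = opt$p_correct,
    mean_dt_opt = opt$mean_dt
  )
}

#' Heatmap of a fitness landscape
#'
#' @param object An `sprt_landscape`.
#' @param ... Unused.
#' @return A ggplot: fitness raster over (theta, phi) with the optimum
#'   marked. Invalid cells are blank.
#' @export
autoplot.sprt_landscape <- function(object, ...) {
  cells <- tidy(object)
  cells$fitness[!cells$valid] <- NA_real_
  opt <- find_optimum(object)
  ggplot2::ggplot(cells, ggplot2::aes(.data$theta, .data$phi)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fitness)) +
    ggplot2::geom_point(data = opt, colour = "black", size = 2) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      x = expression(theta), y = expression(phi), fill = "fitness",
      title = "Fitness landscape",
      subtitle = sprintf(
        "optimum at theta* = %g, phi* = %g", opt$theta, opt$phi
      )
    )
}

#' Write a landscape as a tab-delimited table
#'
#' One row per cell with columns `theta`, `phi`, `p_correct`, `mean_dt`,
#' `c_effort`, `fitness`, `valid`; header row, LF line endings, full
#' floating precision.
#'
#' @param landscape An `sprt_landscape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "sprt_landscape"))
  readr::write_tsv(tidy(landscape), path)
  invisible(path)
}
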