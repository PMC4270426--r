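#' Default run configuration
#'
#' A flat list of every tunable parameter of a run, with the package's
#' default study scenario: a symmetric evidence environment
#' (`eps_good = 0.75`, `eps_bad = 0.25`, even prior), benefit 10 per
#' correct decision, hyperbolic effort curve with `k = 0.05`, baseline
#' time cost 0.02 (compared against its halved and doubled values), and a
#' 20-point log-spaced time-cost sweep spanning two orders of magnitude.
#'
#' @return A named list of class `sprt_config`.
#' @seealso [load_config()], [write_config()], [sprt_main()]
#' @export
default_config <- function() {
  structure(
    list(
      eps_good = 0.75,
      eps_bad = 0.25,
      prior_good = 0.5,
      benefit = 10,
      c_time = 0.02,
      k = 0.05,
      theta_min = 0.55,
      theta_max = 0.99,
      theta_step = 0.01,
      phi_min = 0,
      phi_max = 0.98,
      phi_step = 0.02,
      n_trials = 10000,
      t_max = 10000,
      seed = 1,
      mode = "oracle",
      c_time_values = c(0.01, 0.02, 0.04),
      c_time_sweep_min = 0.002,
      c_time_sweep_max = 0.2,
      c_time_sweep_n = 20
    ),
    class = "sprt_config"
  )
}

config_numeric_keys <- function() {
  setdiff(names(default_config()), c("mode", "c_time_values"))
}

#' Read a run configuration from a flat key-value file
#'
#' The file format is one `key = value` assignment per line; blank lines
#' and lines starting with `#` are ignored. `c_time_values` takes a
#' comma-separated list; `mode` is `oracle` or `simulate`; every other
#' key is a single number. Missing keys take the documented defaults
#' ([default_config()]); unknown keys are an error, as are values that
#' violate the model's constraints (each error names the offending keys).
#'
#' @param path Path to the configuration file, or `NULL` for pure
#'   defaults.
#' @return A validated `sprt_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("Config file not found: ", path))
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (line in lines) {
      if (!grepl("=", line, fixed = TRUE)) {
        abort(paste0("Config line is not a `key = value` assignment: ", line))
      }
      key <- trimws(sub("=.*$", "", line))
      value <- trimws(sub("^[^=]*=", "", line))
      if (!key %in% names(cfg)) {
        abort(paste0("Unknown config key: `", key, "`."))
      }
      cfg[[key]] <- parse_config_value(key, value)
    }
  }
  validate_config(cfg)
}

parse_config_value <- function(key, value) {
  if (key == "mode") {
    if (!value %in% c("oracle", "simulate")) {
      abort("`mode` must be \"oracle\" or \"simulate\".")
    }
    return(value)
  }
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(trimws(parts)))
  if (any(is.na(num))) {
    abort(paste0("Config key `", key, "` has a non-numeric value: ", value))
  }
  if (key != "c_time_values" && length(num) != 1L) {
    abort(paste0("Config key `", key, "` must be a single number."))
  }
  num
}

validate_config <- function(cfg) {
  if (!(cfg$eps_bad > 0 && cfg$eps_good < 1 && cfg$eps_bad < cfg$eps_good)) {
    abort("Config keys `eps_good` and `eps_bad` must satisfy 0 < eps_bad < eps_good < 1.")
  }
  if (cfg$prior_good <= 0 || cfg$prior_good >= 1) {
    abort("Config key `prior_good` must lie strictly between 0 and 1.")
  }
  if (cfg$benefit < 0) abort("Config key `benefit` must be non-negative.")
  if (cfg$c_time < 0) abort("Config key `c_time` must be non-negative.")
  if (cfg$k <= 0) abort("Config key `k` must be positive.")
  if (!(cfg$theta_min > 0.5 && cfg$theta_max < 1 &&
        cfg$theta_min <= cfg$theta_max && cfg$theta_step > 0)) {
    abort("Config keys `theta_min`, `theta_max`, `theta_step` must define a grid inside (0.5, 1).")
  }
  if (!(cfg$phi_min >= 0 && cfg$phi_max <= 0.98 &&
        cfg$phi_min <= cfg$phi_max && cfg$phi_step > 0)) {
    abort("Config keys `phi_min`, `phi_max`, `phi_step` must define a grid inside [0, 0.98].")
  }
  if (cfg$n_trials < 1) abort("Config key `n_trials` must be at least 1.")
  if (cfg$t_max < 1) abort("Config key `t_max` must be at least 1.")
  if (any(cfg$c_time_values < 0)) {
    abort("Config key `c_time_values` must be non-negative.")
  }
  if (!(cfg$c_time_sweep_min > 0 && cfg$c_time_sweep_max > cfg$c_time_sweep_min &&
        cfg$c_time_sweep_n >= 2)) {
    abort("Config keys `c_time_sweep_min`, `c_time_sweep_max`, `c_time_sweep_n` must define an increasing sweep.")
  }
  cfg
}

#' Write a configuration as a flat key-value file
#'
#' Produces a file that [load_config()] reads back to an identical
#' configuration, so every output directory carries the exact effective
#' settings that produced it.
#'
#' @param cfg An `sprt_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(key) {
    value <- cfg[[key]]
    value <- if (is.character(value)) value else {
      paste(format(value, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = ",")
    }
    paste0(key, " = ", value)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

config_environment <- function(cfg) {
  sprt_environment(
    eps_good = cfg$eps_good, eps_bad = cfg$eps_bad,
    prior_good = cfg$prior_good, benefit = cfg$benefit,
    c_time = cfg$c_time
  )
}

config_costs <- function(cfg) cost_model(k = cfg$k)

config_grid <- function(cfg) {
  grid_spec(
    theta = seq(cfg$theta_min, cfg$theta_max, by = cfg$theta_step),
    phi = seq(cfg$phi_min, cfg$phi_max, by = cfg$phi_step),
    n_trials = cfg$n_trials, t_max = cfg$t_max, seed = cfg$seed,
    mode = cfg$mode
  )
}

config_sweep <- function(cfg) {
  log_spaced(cfg$c_time_sweep_min, cfg$c_time_sweep_max, cfg$c_time_sweep_n)
}

#' Command-line entry point
#'
#' Runs one of the package's analyses and writes its tab-delimited output,
#' the effective configuration and a short log to an output directory.
#' Subcommands: `landscape` (fitness landscape table), `optimize` (the
#' optimal cell), `compare` (Type 1 vs Type 2 across time costs),
#' `substitute` (the time/effort substitution curve) and `diagnose`
#' (oracle vs simulation agreement at the baseline optimum). Flags:
#' `--config PATH`, `--seed INT`, `--mode oracle|simulate`, `--out DIR`,
#' `--n-trials INT`.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first), e.g. `c("landscape", "--out", "results")`.
#' @return Exit status, invisibly: 0 on success, 1 on error.
#' @export
sprt_main <- function(argv = character()) {
  status <- tryCatch(
    {
      run_cli(argv)
      0L
    },
    error = function(e) {
      message("sprteffort error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}

parse_cli <- function(argv) {
  subcommands <- c("landscape", "optimize", "compare", "substitute", "diagnose")
  if (length(argv) == 0L || !argv[[1]] %in% subcommands) {
    abort(paste0(
      "Usage: sprteffort <", paste(subcommands, collapse = "|"),
      "> [--config PATH] [--seed INT] [--mode oracle|simulate] ",
      "[--out DIR] [--n-trials INT]"
    ))
  }
  cmd <- argv[[1]]
  args <- argv[-1]
  opts <- list(config = NULL, seed = NULL, mode = NULL, out = ".",
               n_trials = NULL)
  i <- 1L
  while (i <= length(args)) {
    flag <- args[[i]]
    if (!flag %in% c("--config", "--seed", "--mode", "--out", "--n-trials")) {
      abort(paste0("Unknown flag: ", flag))
    }
    if (i == length(args)) abort(paste0("Flag ", flag, " needs a value."))
    value <- args[[i + 1L]]
    key <- sub("^--", "", flag)
    key <- sub("-", "_", key, fixed = TRUE)
    opts[[key]] <- value
    i <- i + 2L
  }
  list(cmd = cmd, opts = opts)
}

run_cli <- function(argv) {
  parsed <- parse_cli(argv)
  opts <- parsed$opts
  cfg <- load_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$mode)) cfg$mode <- opts$mode
  if (!is.null(opts$n_trials)) cfg$n_trials <- as.integer(opts$n_trials)
  cfg <- validate_config(cfg)
  out_dir <- opts$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  env <- config_environment(cfg)
  costs <- config_costs(cfg)
  grid <- config_grid(cfg)
  log_lines <- c(
    paste0("sprteffort ", parsed$cmd),
    paste0("seed = ", cfg$seed, ", mode = ", cfg$mode),
    paste0("grid: ", length(grid$theta), " theta x ", length(grid$phi),
           " phi cells")
  )
  tie_messages <- character()
  withCallingHandlers(
    {
      if (parsed$cmd == "landscape") {
        land <- evaluate_landscape(env, costs, grid)
        write_landscape(land, file.path(out_dir, "landscape.tsv"))
        opt <- find_optimum(land)
        log_lines <- c(log_lines, sprintf(
          "cells = %d, valid = %d, theta* = %g, phi* = %g, fitness = %.6f",
          nrow(land), sum(land$valid), opt$theta, opt$phi, opt$fitness
        ))
      } else if (parsed$cmd == "optimize") {
        land <- evaluate_landscape(env, costs, grid)
        opt <- find_optimum(land)
        readr::write_tsv(opt, file.path(out_dir, "optimum.tsv"))
        log_lines <- c(log_lines, sprintf(
          "theta* = %g, phi* = %g, fitness = %.6f", opt$theta, opt$phi,
          opt$fitness
        ))
      } else if (parsed$cmd == "compare") {
        cmp <- compare_across_time_costs(
          env, costs, grid, c_time_values = cfg$c_time_values,
          baseline = cfg$c_time
        )
        write_comparison(cmp, file.path(out_dir, "comparison.tsv"))
        log_lines <- c(log_lines, sprintf(
          "baseline = %g, phi_fixed = %g, max advantage = %.6f",
          attr(cmp, "baseline"), attr(cmp, "phi_fixed"),
          max(cmp$rel_advantage)
        ))
      } else if (parsed$cmd == "substitute") {
        sub <- substitution_curve(
          env, costs, grid, c_time_values = config_sweep(cfg)
        )
        write_substitution(sub, file.path(out_dir, "substitution.tsv"))
        g <- glance(sub)
        log_lines <- c(log_lines, sprintf(
          "sweep n = %d, DT non-increasing = %s, Ce non-decreasing = %s",
          g$n_costs, g$dt_non_increasing, g$c_effort_non_decreasing
        ))
      } else { # diagnose
        opt <- find_optimum(evaluate_landscape(env, costs, grid))
        pol <- sprt_policy(opt$theta, opt$phi)
        sim <- simulate_ensemble(env, pol, n_trials = cfg$n_trials,
                                 seed = cfg$seed, t_max = cfg$t_max)
        ora <- oracle_summary(env, pol, t_max = cfg$t_max)
        diag <- tibble(
          source = c("oracle", "simulate"),
          theta = opt$theta, phi = opt$phi,
          p_correct = c(ora$p_correct, sim$p_correct),
          mean_dt = c(ora$mean_dt, sim$mean_dt)
        )
        readr::write_tsv(diag, file.path(out_dir, "diagnose.tsv"))
        log_lines <- c(log_lines, sprintf(
          "oracle vs simulate at optimum: dPc = %.5f, dDT = %.4f",
          abs(diff(diag$p_correct)), abs(diff(diag$mean_dt))
        ))
      }
    },
    message = function(m) {
      tie_messages <<- c(tie_messages, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  write_config(cfg, file.path(out_dir, "effective_config.txt"))
  writeLines(c(log_lines, tie_messages), file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}
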