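#' Effort-cost model
#'
#' The accuracy bought by effort saturates: the probability `phi` of an
#' error-free observation is a hyperbolic function of the effort cost paid
#' per sample, `phi = c_effort / (k + c_effort)`, with diminishing returns
#' controlled by the half-saturation constant `k`. The inverse gives the
#' per-sample price of an effort level, `c_effort = k * phi / (1 - phi)`,
#' which diverges as `phi` approaches 1: perfect perception is
#' unaffordable.
#'
#' @param k Saturation constant, in the same cost units as `c_effort`;
#'   the effort cost at which half the perceptual error is eliminated.
#'   Must be positive.
#' @return An object of class `sprt_costs` holding `k`.
#' @examples
#' costs <- cost_model(k = 0.05)
#' phi_from_cost(0.05, k = 0.05)  # half saturation
#' @export
cost_model <- function(k = 0.05) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) abort("`k` must be positive.")
  structure(list(k = k), class = "sprt_costs")
}

#' @export
print.sprt_costs <- function(x, ...) {
  cat(sprintf("<sprt_costs> hyperbolic effort curve, k = %g\n", x$k))
  invisible(x)
}

#' Effort level obtained from a per-sample effort expenditure
#'
#' Hyperbolic saturating map `phi = c_effort / (k + c_effort)`: strictly
#' increasing and concave in `c_effort`, with `phi(0) = 0` and `phi -> 1`
#' as the expenditure grows without bound.
#'
#' @param c_effort Non-negative effort cost paid per sample.
#' @param k Positive saturation constant.
#' @return Effort level in `[0, 1)`. Vectorised over `c_effort`.
#' @seealso [cost_from_phi()] for the exact inverse.
#' @export
phi_from_cost <- function(c_effort, k) {
  stopifnot(is.numeric(c_effort), is.numeric(k), length(k) == 1L)
  if (k <= 0) abort("`k` must be positive.")
  if (any(!is.finite(c_effort)) || any(c_effort < 0)) {
    abort("`c_effort` must be finite and non-negative.")
  }
  c_effort / (k + c_effort)
}

#' Per-sample effort expenditure required for an effort level
#'
#' Exact inverse of [phi_from_cost()]: `c_effort = k * phi / (1 - phi)`.
#' The cost diverges as `phi` approaches 1, which is why effort levels are
#' restricted to `[0, 1)` throughout the package.
#'
#' @param phi Effort level in `[0, 1)`.
#' @param k Positive saturation constant.
#' @return Non-negative cost. Vectorised over `phi`.
#' @export
cost_from_phi <- function(phi, k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k <= 0) abort("`k` must be positive.")
  check_phi(phi)
  k * phi / (1 - phi)
}

#' Total cost of acquiring one sample
#'
#' Each sample costs `c_time + c_effort(phi)`: the baseline cost of the
#' time it takes plus the additional effort spent making the observation
#' accurate.
#'
#' @param c_time Non-negative baseline cost per sample.
#' @param phi Effort level in `[0, 1)`.
#' @param k Positive saturation constant of the effort curve.
#' @return Total per-sample cost. Vectorised over `c_time` and `phi`.
#' @export
per_sample_cost <- function(c_time, phi, k) {
  if (any(!is.finite(c_time)) || any(c_time < 0)) {
    abort("`c_time` must be finite and non-negative.")
  }
  c_time + cost_from_phi(phi, k)
}
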