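#' Thermal performance curve parameters
#'
#' A warm-skewed, unimodal performance curve anchored at an evolving
#' thermal optimum. The lower and upper critical limits sit at fixed
#' offsets from the optimum (`CT_min = z - delta_min`,
#' `CT_max = z + delta_max`), so the whole curve shifts horizontally as
#' the optimum `z` evolves: every rate satisfies
#' `rate(z + c, T + c) = rate(z, T)` to machine precision.
#'
#' The shape is an asymmetric double-Gaussian on the mismatch
#' \eqn{u = T - z}: each flank is a Gaussian with scale tied to its
#' critical-limit offset (\eqn{\sigma = \delta/2.5}), shifted and
#' rescaled so the curve is exactly 1 at the optimum and exactly 0 at
#' the critical limits,
#' \deqn{g_0(u) = \frac{e^{-(u/\sigma_{side})^2} - e^{-2.5^2}}
#'                      {1 - e^{-2.5^2}},}
#' zero outside \eqn{[-\delta_{min}, \delta_{max}]} and continuous on
#' the whole line. A long gentle cold flank and a short steep hot flank
#' give the warm-skewed performance typical of insect vital rates:
#' performance collapses quickly once temperature exceeds the optimum.
#'
#' @param delta_min Offset from optimum down to the lower critical limit
#'   (degrees C, > 0).
#' @param delta_max Offset from optimum up to the upper critical limit
#'   (degrees C, > 0).
#' @param peak_rate Rate at the optimum (per day, >= 0).
#' @param m0 Baseline (minimum) mortality at the optimum (per day).
#' @param m1 Mortality rise toward the critical limits (per day); realized
#'   mortality is `m0 + m1 * (1 - g0)`.
#' @return An object of class `tpc_params`.
#' @examples
#' tp <- tpc_params(peak_rate = 0.3)
#' birth_rate(z = 20, T = 20, tp)   # peak_rate at the optimum
#' birth_rate(z = 20, T = 26, tp)   # zero at the upper critical limit
#' @export
tpc_params <- function(delta_min = 18, delta_max = 6, peak_rate = 0.3,
                       m0 = 0.02, m1 = 0.2) {
  stopifnot(delta_min > 0, delta_max > 0, peak_rate >= 0, m0 >= 0, m1 >= 0)
  structure(list(delta_min = delta_min, delta_max = delta_max,
                 peak_rate = peak_rate, m0 = m0, m1 = m1),
            class = "tpc_params")
}

# normalized shape on the mismatch u = T - z: 1 at u = 0, 0 outside
# [-delta_min, delta_max]; compiled kernel (the simulation evaluates it
# ~10^4 times per simulated day)
tpc_shape <- function(u, delta_min, delta_max) {
  out <- tpc_shape_cpp(as.numeric(u), delta_min, delta_max)
  if (!is.null(dim(u))) dim(out) <- dim(u)
  out
}

#' Temperature-dependent vital rates
#'
#' `birth_rate()` is the TPC-scaled birth rate `peak_rate * g0(T - z)`;
#' `mortality_rate()` is `m0 + m1 * (1 - g0(T - z))`, minimal at the
#' optimum and rising to `m0 + m1` at and beyond the critical limits;
#' `predation_scaler()` is the bare shape `g0` on the unit interval, used
#' to modulate the predator's functional response.
#'
#' All three are vectorized over `z` and `T` and shift-equivariant:
#' `rate(z + c, T + c) == rate(z, T)`.
#'
#' @param z Thermal optimum phenotype (degrees C).
#' @param T Environmental temperature (degrees C).
#' @param params A [tpc_params()] object.
#' @return Numeric rate(s): per day for the vital rates, dimensionless in
#'   \[0, 1\] for `predation_scaler()`.
#' @export
birth_rate <- function(z, T, params) {
  params$peak_rate * tpc_shape(T - z, params$delta_min, params$delta_max)
}

#' @rdname birth_rate
#' @export
mortality_rate <- function(z, T, params) {
  params$m0 + params$m1 *
    (1 - tpc_shape(T - z, params$delta_min, params$delta_max))
}

#' @rdname birth_rate
#' @export
predation_scaler <- function(z, T, params) {
  tpc_shape(T - z, params$delta_min, params$delta_max)
}

#' Ecological interaction parameters
#'
#' @param a Predator searching rate (per predator per day).
#' @param h Handling time (days per prey item); per-predator consumption
#'   saturates at `1/h` prey per day.
#' @param qp Prey items consumed per predator egg (numerical response
#'   conversion).
#' @param K Prey (aphid) carrying capacity.
#' @return An object of class `eco_params`.
#' @examples
#' eco_params()
#' @export
eco_params <- function(a = 1e-7, h = 0.02, qp = 50, K = 5e7) {
  stopifnot(a > 0, h > 0, qp > 0, K > 0)
  structure(list(a = a, h = h, qp = qp, K = K), class = "eco_params")
}

#' Temperature-modified type-II functional response
#'
#' Per-predator per-prey capture rate
#' \deqn{\beta(z, T, A) = g_0(T - z)\,\frac{a}{1 + a h A},}
#' a Holling type-II response scaled by the predator's thermal performance.
#' Total per-predator consumption `beta * A` saturates at `g0 / h` as prey
#' abundance `A` grows.
#'
#' @inheritParams birth_rate
#' @param A Prey abundance (>= 0).
#' @param eco An [eco_params()] object.
#' @return Capture rate per predator per prey per day.
#' @examples
#' functional_response(20, 20, A = 1e6, tpc_params(), eco_params())
#' @export
functional_response <- function(z, T, A, params, eco) {
  stopifnot(all(A >= 0))
  predation_scaler(z, T, params) * eco$a / (1 + eco$a * eco$h * A)
}
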