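#' Discretized breeding-value distribution
#'
#' The object selection acts on: a probability density of breeding values
#' `z_g` (degrees C of thermal optimum) tabulated on a uniform grid. The
#' density integrates to 1 by the trapezoid rule. A zero-variance
#' population is represented as a degenerate point mass (a single grid
#' point with unit mass), which every operation treats as the exact
#' delta-function limit.
#'
#' @param grid Strictly increasing, uniformly spaced numeric vector of
#'   breeding values (degrees C), or a single value for a point mass.
#' @param density Non-negative weights on `grid`; renormalized to
#'   integrate to 1.
#' @return An object of class `bv_dist` with fields `grid`, `density`,
#'   `dx`, `degenerate`.
#' @examples
#' d <- bv_dist_normal(mean = 19, var = 0.3)
#' bv_mean(d); bv_var(d)
#' @export
bv_dist <- function(grid, density) {
  grid <- as.numeric(grid)
  density <- as.numeric(density)
  stopifnot(length(grid) == length(density), all(is.finite(grid)))
  if (any(density < 0)) stop("density must be non-negative")
  if (length(grid) == 1) {
    return(structure(list(grid = grid, density = 1, dx = NA_real_,
                          degenerate = TRUE), class = "bv_dist"))
  }
  dg <- diff(grid)
  if (any(dg <= 0)) stop("grid must be strictly increasing")
  if (max(dg) - min(dg) > 1e-9 * mean(dg)) stop("grid must be uniform")
  dx <- mean(dg)
  tot <- trapz_uniform(density, dx)
  if (tot <= 0) stop("density has zero total mass")
  structure(list(grid = grid, density = density / tot, dx = dx,
                 degenerate = FALSE), class = "bv_dist")
}

#' @export
print.bv_dist <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<bv_dist> point mass at %.4f C\n", x$grid))
  } else {
    cat(sprintf(
      "<bv_dist> %d points on [%.3f, %.3f] C, mean %.4f, var %.5f\n",
      length(x$grid), x$grid[1], x$grid[length(x$grid)],
      bv_mean(x), bv_var(x)))
  }
  invisible(x)
}

# trapezoid integral of values tabulated on a uniform grid
trapz_uniform <- function(v, dx) {
  n <- length(v)
  if (n == 1) return(v)
  dx * (sum(v) - 0.5 * (v[1] + v[n]))
}

# integral of f * density for a bv_dist (expectation of f under the dist)
bv_integrate <- function(dist, f_vals) {
  if (dist$degenerate) return(sum(f_vals * dist$density))
  trapz_uniform(f_vals * dist$density, dist$dx)
}

#' Gaussian breeding-value distribution on a fresh grid
#'
#' Builds a normal density on a uniform grid spanning
#' `mean +/- span_sd * sqrt(var)` (default 8 standard deviations, 601
#' points, so the spacing is well under sd/8 and edge densities are below
#' 1e-10). `var = 0` gives the degenerate point mass.
#'
#' @param mean Mean breeding value (degrees C).
#' @param var Variance (degrees C squared, >= 0).
#' @param n Number of grid points.
#' @param span_sd Half-width of the grid in standard deviations.
#' @param sd_floor Minimum sd used for the grid span (guards against
#'   collapsing grids when `var` is tiny but non-zero).
#' @return A `bv_dist`.
#' @export
bv_dist_normal <- function(mean, var, n = 601, span_sd = 8,
                           sd_floor = 0) {
  stopifnot(var >= 0)
  if (var == 0) return(bv_dist(mean, 1))
  sd_span <- max(sqrt(var), sd_floor)
  grid <- seq(mean - span_sd * sd_span, mean + span_sd * sd_span,
              length.out = n)
  bv_dist(grid, stats::dnorm(grid, mean, sqrt(var)))
}

#' Moments of a breeding-value distribution
#'
#' Trapezoid-rule mean and variance of a [bv_dist()].
#'
#' @param dist A `bv_dist`.
#' @return A scalar (degrees C for the mean, squared degrees C for the
#'   variance).
#' @export
bv_mean <- function(dist) {
  bv_integrate(dist, dist$grid)
}

#' @rdname bv_mean
#' @export
bv_var <- function(dist) {
  if (dist$degenerate) return(0)
  m <- bv_mean(dist)
  max(bv_integrate(dist, (dist$grid - m)^2), 0)
}

# total trapezoid mass (should be 1 for a valid bv_dist)
bv_mass <- function(dist) {
  if (dist$degenerate) return(sum(dist$density))
  trapz_uniform(dist$density, dist$dx)
}

assert_normalized <- function(dist, tol = 1e-6, what = "distribution") {
  if (abs(bv_mass(dist) - 1) > tol) {
    stop(what, " is not normalized (trapezoid mass = ",
         format(bv_mass(dist)), ")")
  }
  invisible(dist)
}

#' Reweight a breeding-value distribution
#'
#' Multiplies the density by non-negative pointwise weights and
#' renormalizes -- the elementary selection update underlying both
#' species' selection equations. With Gaussian weights this is the
#' conjugate-Gaussian (Bayes) update.
#'
#' @param dist A normalized `bv_dist`.
#' @param weights Non-negative weights on `dist$grid`. Negative values
#'   (possible when a fitness multiplier `1 + w * dt` dips below zero in
#'   far tails) are floored at zero: a lineage density cannot be negative.
#' @return A normalized `bv_dist` on the same grid.
#' @export
bv_reweight <- function(dist, weights) {
  stopifnot(length(weights) == length(dist$grid))
  if (dist$degenerate) return(dist)
  d <- dist$density * pmax(weights, 0)
  tot <- trapz_uniform(d, dist$dx)
  if (!is.finite(tot) || tot <= 0) {
    stop("selection annihilated the distribution (total mass <= 0)",
         call. = FALSE)
  }
  dist$density <- d / tot
  dist
}

#' Species genetic state
#'
#' Tracks the quantities of the infinitesimal-model bookkeeping for one
#' species: mean breeding value `mean_g` (z-bar_g), additive genetic
#' variance `var_g` (V_g), segregation variance `var_g0` (V_g0, the
#' variance restored by meiotic segregation under the infinitesimal
#' model), the Bulmer deviation `dev` (d, the transient departure of V_g
#' from V_g0 caused by selection), environmental variance `var_e` (V_e),
#' mutational heritability `h2m`, the generations-per-day coefficient
#' `eta`, and (for the prey) the inbreeding coefficient `inbreeding_f`
#' discounting restored variance during the annual sexual phase. The
#' per-day mutational variance input is `var_tau = eta * h2m * var_e`.
#'
#' @param mean_g Mean breeding value (degrees C).
#' @param var_g0 Segregation variance (degrees C squared, >= 0).
#' @param var_e Environmental variance (degrees C squared, >= 0).
#' @param h2m Mutational heritability (dimensionless).
#' @param eta Generations per day.
#' @param inbreeding_f Inbreeding coefficient in \[0, 1): 0 for the
#'   predator, ~0.1 for the prey.
#' @param var_g Initial additive genetic variance; defaults to `var_g0`.
#' @param dev Initial Bulmer deviation; defaults to 0.
#' @return An object of class `genetic_state`.
#' @examples
#' genetic_state(mean_g = 19)
#' @export
genetic_state <- function(mean_g, var_g0 = 0.3, var_e = 0.7, h2m = 1e-3,
                          eta = 1 / 7, inbreeding_f = 0,
                          var_g = var_g0, dev = 0) {
  stopifnot(var_g0 >= 0, var_e >= 0, var_g >= 0, h2m >= 0, eta >= 0,
            inbreeding_f >= 0, inbreeding_f < 1)
  structure(
    list(mean_g = mean_g, var_g = var_g, var_g0 = var_g0, dev = dev,
         var_e = var_e, h2m = h2m, eta = eta,
         var_tau = eta * h2m * var_e, inbreeding_f = inbreeding_f),
    class = "genetic_state"
  )
}

#' @export
print.genetic_state <- function(x, ...) {
  cat(sprintf(
    "<genetic_state> mean_g = %.4f C, var_g = %.5f (var_g0 = %.3f, dev = %+.2e), var_e = %.3f, var_tau = %.2e/day, f = %.2f\n",
    x$mean_g, x$var_g, x$var_g0, x$dev, x$var_e, x$var_tau,
    x$inbreeding_f))
  invisible(x)
}

# Environmentally smoothed TPC shape S(u) = E_ze[g0(u - ze)],
# ze ~ Normal(0, var_e): the exact Gaussian convolution of the shape,
# evaluated once by FFT on a fine uniform mismatch grid (dz = 2.5e-4 C,
# fine enough that the trapezoid treatment of the critical-limit cusp
# contributes < 1e-6) and then interpolated cubically. Cached per
# (var_e, delta_min, delta_max). Gauss-Hermite quadrature is NOT used
# here: the shape's cusps at the critical limits defeat its smoothness
# assumption (node-crossing oscillations of order 1e-2).
shape_table_cache <- new.env(parent = emptyenv())
smoothed_shape_table <- function(var_e, delta_min, delta_max,
                                 dz = 2.5e-4) {
  key <- paste(var_e, delta_min, delta_max, dz, sep = "|")
  tab <- shape_table_cache[[key]]
  if (is.null(tab)) {
    sigma <- sqrt(var_e)
    nk <- ceiling(7 * sigma / dz)
    half <- nk * dz
    kz <- (-nk:nk) * dz # symmetric, odd length
    w <- stats::dnorm(kz, 0, sigma)
    w <- w / sum(w)
    u <- seq(-delta_min - half - dz, delta_max + half + dz, by = dz)
    g <- tpc_shape_cpp(u, delta_min, delta_max)
    conv <- stats::convolve(g, rev(w), type = "open")
    m <- length(w)
    S <- conv[((m + 1) / 2):((m + 1) / 2 + length(u) - 1)]
    tab <- list(S = S, u0 = u[1], du = dz)
    shape_table_cache[[key]] <- tab
  }
  tab
}

#' Population mean vital rates across genetic and environmental variation
#'
#' Computes the population means that drive the coupled dynamics by
#' integrating each rate over the breeding-value density (trapezoid on the
#' grid) and the environmental-effect distribution Normal(0, V_e) (exact
#' Gaussian convolution of the thermal performance shape, precomputed on
#' a fine mismatch grid):
#' * `Fbar` -- mean aphid lineage growth excluding predation,
#'   \eqn{\bar F = E[f(z)(1 - A/K) - \mu(z)]};
#' * `Bbar` -- mean per-aphid predation loss,
#'   \eqn{\bar B = \bar g\, aL / (1 + ahA)};
#' * `wbar_l` -- mean ladybird lineage growth,
#'   \eqn{\bar w_L = \bar g\, aA / ((1 + ahA) Q_p) - \bar\gamma};
#' * `beta_bar` -- the mean functional response \eqn{\bar g a/(1 + ahA)},
#'   evaluated once and reused in both the prey-loss and the
#'   predator-recruitment terms.
#'
#' Also returns the conditional means given breeding value (environmental
#' effects integrated out): `F_of_zg` and `w_of_zg`, the fitness surfaces
#' selection acts on.
#'
#' @param dist_a,dist_l Breeding-value distributions ([bv_dist()]) for
#'   aphid and ladybird; must be normalized.
#' @param gen_a,gen_l [genetic_state()] objects (used for `var_e`).
#' @param T Temperature (degrees C).
#' @param A,L Aphid and ladybird abundance (>= 0).
#' @param tpc_a,tpc_l [tpc_params()] for each species.
#' @param eco An [eco_params()] object.
#' @return A list with elements `Fbar`, `Bbar`, `wbar_l`, `beta_bar`,
#'   `gbar`, `F_of_zg`, `w_of_zg`.
#' @export
mean_rates <- function(dist_a, dist_l, gen_a, gen_l, T, A, L,
                       tpc_a, tpc_l, eco) {
  stopifnot(A >= 0, L >= 0)
  assert_normalized(dist_a, what = "aphid distribution")
  assert_normalized(dist_l, what = "ladybird distribution")

  # E_ze[shape(T - (zg + ze))] for each zg: both the birth and mortality
  # rates (and the predation scaler) are affine in the same TPC shape, so
  # one integral per species suffices. The integral depends on the
  # breeding value only through the mismatch T - zg, so the smoothed
  # shape is tabulated once per (var_e, TPC) and interpolated.
  shape_of_zg <- function(dist, gen, tpc) {
    if (gen$var_e == 0) {
      return(tpc_shape(T - dist$grid, tpc$delta_min, tpc$delta_max))
    }
    tab <- smoothed_shape_table(gen$var_e, tpc$delta_min, tpc$delta_max)
    interp_table_cpp(tab$S, tab$u0, tab$du, T - dist$grid)
  }

  s_a <- shape_of_zg(dist_a, gen_a, tpc_a)
  F_of_zg <- s_a * (tpc_a$peak_rate * (1 - A / eco$K) + tpc_a$m1) -
    (tpc_a$m0 + tpc_a$m1)
  Fbar <- bv_integrate(dist_a, F_of_zg)

  s_l <- shape_of_zg(dist_l, gen_l, tpc_l)
  denom <- 1 + eco$a * eco$h * A
  gbar <- bv_integrate(dist_l, s_l)
  beta_bar <- gbar * eco$a / denom
  Bbar <- beta_bar * L
  consume <- eco$a * A / denom # prey consumed per predator per unit g
  w_of_zg <- s_l * (consume / eco$qp + tpc_l$m1) - (tpc_l$m0 + tpc_l$m1)
  wbar_l <- bv_integrate(dist_l, w_of_zg)

  list(Fbar = Fbar, Bbar = Bbar, wbar_l = wbar_l, beta_bar = beta_bar,
       gbar = gbar, F_of_zg = F_of_zg, w_of_zg = w_of_zg)
}

#' Selection update of the ladybird breeding-value distribution
#'
#' One time step of selection on the predator:
#' \deqn{\rho'(z_g) = \rho(z_g)\,\frac{1 + \Delta t\, \bar w_L(z_g)}
#'                                    {1 + \Delta t\, \bar w_L},}
#' where `fitness_of_zg` is the lineage growth rate with environmental
#' effects already integrated out (the `w_of_zg` surface from
#' [mean_rates()]).
#'
#' @param dist A normalized `bv_dist`.
#' @param fitness_of_zg Per-day lineage growth rate at each grid point.
#' @param wbar Population mean of `fitness_of_zg` under `dist`.
#' @param dt Time step in days.
#' @return A normalized `bv_dist`.
#' @export
select_ladybird <- function(dist, fitness_of_zg, wbar, dt) {
  if (1 + wbar * dt <= 0) {
    stop(structure(
      class = c("evorescue_collapse", "error", "condition"),
      list(message = "ladybird mean growth multiplier <= 0: population collapse",
           call = sys.call())))
  }
  bv_reweight(dist, 1 + dt * fitness_of_zg)
}

#' Selection update of the aphid breeding-value distribution
#'
#' One time step of selection on the prey during the asexual phase:
#' \deqn{\rho'(z_g) = \rho(z_g)\,\frac{1 + \Delta t\,\bar F(z_g) -
#'   \Delta t\,\bar B_L}{1 + (\bar F_A - \bar B_L)\Delta t}.}
#' Predation enters as a phenotype-independent constant \eqn{\bar B_L}:
#' to leading order in \eqn{\Delta t} it only rescales the density, with
#' an O(\eqn{\Delta t^2}) effect on the moments.
#'
#' @param dist A normalized `bv_dist`.
#' @param F_of_zg Aphid lineage growth surface (predation excluded) at
#'   each grid point, environmental effects integrated out.
#' @param Bbar Mean predation loss rate (per day).
#' @param Fbar Population mean of `F_of_zg` under `dist`.
#' @param dt Time step in days.
#' @return A normalized `bv_dist`.
#' @export
select_aphid <- function(dist, F_of_zg, Bbar, Fbar, dt) {
  if (1 + (Fbar - Bbar) * dt <= 0) {
    stop(structure(
      class = c("evorescue_collapse", "error", "condition"),
      list(message = "aphid mean growth multiplier <= 0: population collapse",
           call = sys.call())))
  }
  bv_reweight(dist, 1 + dt * F_of_zg - dt * Bbar)
}

#' Mutational broadening of the aphid breeding-value distribution
#'
#' Convolves the density with a centred normal mutation kernel of
#' variance `var_tau_step`, preserving total mass and mean and increasing
#' the variance by exactly `var_tau_step`. When the kernel sd is at least
#' two grid cells the convolution is evaluated with a discretized
#' Gaussian kernel matrix (column-normalized, spectrally accurate on a
#' uniform grid); when it is narrower -- the usual case for the small
#' per-day mutational input -- the equivalent diffusion step
#' \eqn{\rho \mathrel{+}= (v/2)\,\partial^2 \rho/\partial z^2} is applied
#' in mass-conserving flux form with enough substeps for stability.
#'
#' @param dist A normalized `bv_dist`.
#' @param var_tau_step Mutational variance to add (degrees C squared,
#'   >= 0); typically `var_tau * dt`.
#' @return A normalized `bv_dist` on the same grid.
#' @export
mutate_aphid <- function(dist, var_tau_step) {
  stopifnot(var_tau_step >= 0)
  if (var_tau_step == 0) return(dist)
  if (dist$degenerate) {
    # delta function convolved with the kernel is the kernel itself
    return(bv_dist_normal(dist$grid, var_tau_step))
  }
  dx <- dist$dx
  sdk <- sqrt(var_tau_step)
  if (sdk >= 2 * dx) {
    # dense kernel convolution; columns normalized so mass is conserved
    # exactly despite truncation at the grid boundary
    K <- stats::dnorm(outer(dist$grid, dist$grid, "-"), 0, sdk) * dx
    K <- sweep(K, 2, colSums(K), "/")
    dist$density <- drop(K %*% dist$density)
  } else {
    # explicit diffusion substeps, flux form (Neumann ends): conserves
    # mass to machine precision and adds var_tau_step of variance up to
    # boundary terms of the order of the (negligible) edge density
    nsub <- max(1L, ceiling(var_tau_step / (0.4 * dx^2)))
    alpha <- var_tau_step / (2 * nsub) / dx^2
    d <- dist$density
    n <- length(d)
    for (i in seq_len(nsub)) {
      flux <- diff(d)                       # length n-1
      d <- d + alpha * (c(flux, 0) - c(0, flux))
    }
    dist$density <- d
  }
  tot <- trapz_uniform(dist$density, dx)
  dist$density <- dist$density / tot
  dist
}

#' Bulmer update of the ladybird genetic state after selection
#'
#' Implements the infinitesimal-model bookkeeping for the continuously,
#' sexually reproducing predator. Given the post-selection distribution:
#' the new mean and variance are read off the distribution; mutational
#' variance `var_tau * dt` is added; the change in genetic variance over
#' the step, `delta_vg`, feeds the Bulmer deviation recursion
#' \deqn{d' = d/2 + \Delta V_g,} and random mating restores the variance
#' to `var_g0 + d'` (floored at zero, with a warning when flooring
#' triggers). The working breeding-value distribution is then reset to
#' Normal(mean', var_g_new) by the caller (see [genetic_dist()]).
#'
#' @param state A [genetic_state()].
#' @param dist_after_selection The selected `bv_dist`.
#' @param dt Time step in days.
#' @return The updated `genetic_state`.
#' @export
update_ladybird_genetics <- function(state, dist_after_selection, dt) {
  assert_normalized(dist_after_selection, what = "selected distribution")
  m <- bv_mean(dist_after_selection)
  vg_sel <- bv_var(dist_after_selection)
  vG <- vg_sel + state$var_tau * dt
  delta_vg <- vG - state$var_g
  dev_new <- 0.5 * state$dev + delta_vg
  vg_new <- state$var_g0 + dev_new
  if (vg_new < 0) {
    warning("ladybird V_g floored at 0 (V_g0 + d = ",
            format(vg_new), ")")
    vg_new <- 0
  }
  state$mean_g <- m
  state$var_g <- vg_new
  state$dev <- dev_new
  state
}

#' Annual sexual-phase reset of the aphid genetic state
#'
#' Applied exactly once per year when the prey switches to its sexual
#' generation. The season's accumulated change in genetic variance
#' `delta_vg_year` (end-of-asexual-phase variance minus last year's)
#' feeds the annual Bulmer recursion with inbreeding discount
#' \deqn{d_l = \frac{1-f}{2} d_{l-1} + \Delta V_{g,year},} and
#' segregation plus random mating (with inbreeding) restores
#' \deqn{V_{g,l} = (1-f) V_{g,0} + d_l + V_\tau} (floored at zero). With
#' `nested = TRUE` the alternative parenthesization
#' \eqn{V_{g,l} = (1-f)(V_{g,0} + d_l) + V_\tau} is used instead. The
#' mean breeding value is preserved from the end-of-season distribution.
#'
#' @param state A [genetic_state()] (must have `inbreeding_f` set).
#' @param delta_vg_year Change in genetic variance over the asexual phase
#'   (degrees C squared).
#' @param dist End-of-season `bv_dist` (supplies the preserved mean).
#' @param nested Parenthesization flag for the variance restoration (see
#'   Details).
#' @return The updated `genetic_state`.
#' @export
sexual_reset_aphid <- function(state, delta_vg_year, dist,
                               nested = FALSE) {
  assert_normalized(dist, what = "end-of-season distribution")
  f <- state$inbreeding_f
  dev_new <- (1 - f) / 2 * state$dev + delta_vg_year
  vg_new <- if (nested) {
    (1 - f) * (state$var_g0 + dev_new) + state$var_tau
  } else {
    (1 - f) * state$var_g0 + dev_new + state$var_tau
  }
  if (vg_new < 0) {
    warning("aphid V_g floored at 0 at sexual reset (", format(vg_new), ")")
    vg_new <- 0
  }
  state$mean_g <- bv_mean(dist)
  state$var_g <- vg_new
  state$dev <- dev_new
  state
}

#' Gaussian working distribution implied by a genetic state
#'
#' The infinitesimal-model reset: a normal breeding-value distribution
#' with the state's current mean and variance, on a fresh grid.
#'
#' @param state A [genetic_state()].
#' @param n,span_sd Grid resolution and half-width, as in
#'   [bv_dist_normal()].
#' @param sd_floor Minimum grid-span sd; defaults to `sqrt(var_g0)` so a
#'   transiently small V_g does not collapse the grid.
#' @return A `bv_dist`.
#' @export
genetic_dist <- function(state, n = 601, span_sd = 8, sd_floor = NULL) {
  if (is.null(sd_floor)) sd_floor <- sqrt(state$var_g0)
  bv_dist_normal(state$mean_g, state$var_g, n = n, span_sd = span_sd,
                 sd_floor = sd_floor)
}

# --- grid maintenance -------------------------------------------------

# shift the grid window by an integer number of cells so that
# `target_mean` is within one cell of the grid centre; density values keep
# their absolute positions (moments exactly preserved apart from any
# discarded tail mass, which the edge-density guard keeps < 1e-10)
bv_recenter <- function(dist, target_mean) {
  if (dist$degenerate) return(dist)
  n <- length(dist$grid)
  centre <- (dist$grid[1] + dist$grid[n]) / 2
  k <- round((target_mean - centre) / dist$dx)
  if (k == 0) return(dist)
  new_grid <- dist$grid + k * dist$dx
  idx <- seq_len(n) + k
  new_density <- rep(0, n)
  ok <- idx >= 1 & idx <= n
  new_density[ok] <- dist$density[idx[ok]]
  tot <- trapz_uniform(new_density, dist$dx)
  if (tot <= 0) stop("recentering lost all density mass")
  dist$grid <- new_grid
  dist$density <- new_density / tot
  dist
}

# widen the grid by n_add cells on each side (zero-padded): exact
bv_extend <- function(dist, n_add = 50L) {
  if (dist$degenerate) return(dist)
  dx <- dist$dx
  left <- seq(dist$grid[1] - n_add * dx, by = dx, length.out = n_add)
  right <- seq(dist$grid[length(dist$grid)] + dx, by = dx,
               length.out = n_add)
  dist$grid <- c(left, dist$grid, right)
  dist$density <- c(rep(0, n_add), dist$density, rep(0, n_add))
  dist
}

# guard used after grid-shape-changing operations: recenter when the mean
# has drifted more than one cell from the window centre, extend when edge
# density is non-negligible
bv_maintain <- function(dist, edge_tol = 1e-10) {
  if (dist$degenerate) return(dist)
  m <- bv_mean(dist)
  n <- length(dist$grid)
  if (abs(m - (dist$grid[1] + dist$grid[n]) / 2) > dist$dx) {
    dist <- bv_recenter(dist, m)
    n <- length(dist$grid)
  }
  if (max(dist$density[1], dist$density[n]) > edge_tol) {
    dist <- bv_extend(dist)
  }
  dist
}
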