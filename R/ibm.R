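#' Individual-based populations for the Monte Carlo oracle
#'
#' A validation-only stochastic counterpart of the deterministic
#' integral updates: populations are finite lists of breeding values,
#' each individual draws a fresh environmental effect every exposure,
#' and birth/death events are Bernoulli with probability `rate * dt`.
#' Abundance is `length(z_g) * scale`, so large abundances are
#' represented by a capped number of particles with a scaling factor
#' (populations exceeding `cap` are uniformly subsampled, which is
#' unbiased for the tracked trajectories).
#'
#' @param z_g Numeric vector of breeding values (degrees C), one per
#'   particle.
#' @param scale Abundance represented by each particle.
#' @param pop An `ibm_population`.
#' @return An object of class `ibm_population`.
#' @examples
#' p <- ibm_population(rnorm(100, 19, sqrt(0.3)))
#' ibm_abundance(p)
#' @export
ibm_population <- function(z_g, scale = 1) {
  stopifnot(is.numeric(z_g), scale > 0)
  structure(list(z_g = as.numeric(z_g), scale = scale),
            class = "ibm_population")
}

#' @rdname ibm_population
#' @export
ibm_abundance <- function(pop) {
  length(pop$z_g) * pop$scale
}

ibm_subsample <- function(pop, cap) {
  n <- length(pop$z_g)
  if (n <= cap) return(pop)
  keep <- sample.int(n, cap)
  pop$scale <- pop$scale * n / cap
  pop$z_g <- pop$z_g[keep]
  pop
}

#' One day of the stochastic predator-prey dynamics
#'
#' Each aphid draws a fresh environmental effect, reproduces clonally
#' with probability `f(z) (1 - A/K) dt`, and dies with probability
#' `(mu(z) + B_j) dt`, where its predation hazard `B_j` uses the
#' phenotype of a randomly paired ladybird. Each ladybird draws its own
#' environmental effect, produces an egg with probability
#' `g(z) a A / ((1 + a h A) Q_p) dt`, and dies with probability
#' `gamma(z) dt`; offspring breeding values are midparent (two uniformly
#' drawn parents) plus a segregation deviate Normal(0, `var_g0 / 2`), so
#' that offspring variance equals `var_g0` at linkage equilibrium with no
#' selection-induced deviation. Because the deterministic pipeline
#' assumes the predator population random-mates within every time step
#' (its breeding-value distribution is reset to the implied normal each
#' step), the oracle mirrors that assumption: with `remate = TRUE` (the
#' default) the whole surviving predator pool is replaced by
#' midparent-plus-segregation draws each step, which preserves the mean
#' exactly and restores the segregation variance. Both species then
#' receive the per-day mutational input as a Normal(0, `var_tau * dt`)
#' perturbation of every breeding value.
#'
#' @param pop_a,pop_l [ibm_population()] objects (prey, predator).
#' @param T Temperature (degrees C).
#' @param dt Time step in days; every event probability must stay below
#'   1 or the step aborts with instructions to reduce `dt`.
#' @param config A [default_config()] list (species, ecology and genetic
#'   parameters).
#' @param cap Particle cap per species (subsample above it).
#' @param remate Re-mate the whole predator pool every step (the
#'   infinitesimal-model assumption of the deterministic pipeline).
#' @return A list `list(pop_a, pop_l)` of updated populations.
#' @export
ibm_step <- function(pop_a, pop_l, T, dt = 1, config = default_config(),
                     cap = 1e5, remate = TRUE) {
  tpc_a <- tpc_from_config(config, "aphid")
  tpc_l <- tpc_from_config(config, "ladybird")
  eco <- eco_from_config(config)
  A <- ibm_abundance(pop_a)
  L <- ibm_abundance(pop_l)
  denom <- 1 + eco$a * eco$h * A

  na <- length(pop_a$z_g)
  nl <- length(pop_l$z_g)

  if (na > 0) {
    ze <- stats::rnorm(na, 0, sqrt(config$aphid$var_e))
    s <- tpc_shape(T - (pop_a$z_g + ze), tpc_a$delta_min, tpc_a$delta_max)
    pb <- tpc_a$peak_rate * s * max(1 - A / eco$K, 0) * dt
    # predation hazard through a randomly paired predator
    if (nl > 0 && L > 0) {
      j <- sample.int(nl, na, replace = TRUE)
      ze_l <- stats::rnorm(na, 0, sqrt(config$ladybird$var_e))
      gpair <- tpc_shape(T - (pop_l$z_g[j] + ze_l), tpc_l$delta_min,
                         tpc_l$delta_max)
      B <- gpair * eco$a * L / denom
    } else {
      B <- 0
    }
    pd <- (tpc_a$m0 + tpc_a$m1 * (1 - s) + B) * dt
    check_probs(c(pb, pd), dt)
    born <- stats::runif(na) < pb
    dead <- stats::runif(na) < pd
    pop_a$z_g <- c(pop_a$z_g[!dead], pop_a$z_g[born])
    if (config$aphid$var_g0 > 0 && length(pop_a$z_g) > 0) {
      vtau <- config$aphid$eta * config$aphid$h2m * config$aphid$var_e
      pop_a$z_g <- pop_a$z_g +
        stats::rnorm(length(pop_a$z_g), 0, sqrt(vtau * dt))
    }
    pop_a <- ibm_subsample(pop_a, cap)
  }

  if (nl > 0) {
    ze <- stats::rnorm(nl, 0, sqrt(config$ladybird$var_e))
    s <- tpc_shape(T - (pop_l$z_g + ze), tpc_l$delta_min, tpc_l$delta_max)
    pb <- s * eco$a * A / (denom * eco$qp) * dt
    pd <- (tpc_l$m0 + tpc_l$m1 * (1 - s)) * dt
    check_probs(c(pb, pd), dt)
    born <- stats::runif(nl) < pb
    dead <- stats::runif(nl) < pd
    n_off <- sum(born)
    offspring <- if (n_off > 0) {
      p1 <- pop_l$z_g[sample.int(nl, n_off, replace = TRUE)]
      p2 <- pop_l$z_g[sample.int(nl, n_off, replace = TRUE)]
      (p1 + p2) / 2 +
        stats::rnorm(n_off, 0, sqrt(config$ladybird$var_g0 / 2))
    } else {
      numeric(0)
    }
    pop_l$z_g <- c(pop_l$z_g[!dead], offspring)
    nl2 <- length(pop_l$z_g)
    if (remate && config$ladybird$var_g0 > 0 && nl2 > 1) {
      p1 <- pop_l$z_g[sample.int(nl2, nl2, replace = TRUE)]
      p2 <- pop_l$z_g[sample.int(nl2, nl2, replace = TRUE)]
      pop_l$z_g <- (p1 + p2) / 2 +
        stats::rnorm(nl2, 0, sqrt(config$ladybird$var_g0 / 2))
    }
    if (config$ladybird$var_g0 > 0 && length(pop_l$z_g) > 0) {
      vtau <- config$ladybird$eta * config$ladybird$h2m *
        config$ladybird$var_e
      pop_l$z_g <- pop_l$z_g +
        stats::rnorm(length(pop_l$z_g), 0, sqrt(vtau * dt))
    }
    pop_l <- ibm_subsample(pop_l, cap)
  }

  list(pop_a = pop_a, pop_l = pop_l)
}

check_probs <- function(p, dt) {
  if (length(p) && max(p) > 1) {
    stop("event probability exceeds 1 at dt = ", dt,
         "; reduce the time step", call. = FALSE)
  }
  invisible(TRUE)
}

#' One stochastic growing season for oracle validation
#'
#' Runs the individual-based dynamics from a given season start to a
#' given end day under a location's temperature series, recording daily
#' abundance and mean breeding values. Start days and the predator
#' introduction day are supplied by the caller (normally read off the
#' deterministic run) so that the comparison isolates the coupled
#' selection/abundance updates from phenology.
#'
#' @param config A [default_config()] list.
#' @param climate A [climate_params()] object.
#' @param start_day,end_day First and last simulated day (global day
#'   index).
#' @param lady_day Day the predator population is introduced.
#' @param init_a,init_l Initial abundances.
#' @param z_a,z_l Initial mean breeding values.
#' @param n_particles Particle count for the prey at initialization (and
#'   the subsampling cap).
#' @param seed RNG seed (the function sets the seed; trajectories are
#'   reproducible given the seed).
#' @return A tibble: `day`, `A`, `L`, `mean_g_A`, `mean_g_L`.
#' @export
ibm_run_season <- function(config, climate, start_day, end_day,
                           lady_day, init_a = 1e6, init_l = 5000,
                           z_a, z_l, n_particles = 1e5, seed = 1) {
  set.seed(seed)
  pop_a <- ibm_population(
    stats::rnorm(n_particles, z_a, sqrt(config$aphid$var_g0)),
    scale = init_a / n_particles)
  nl0 <- max(1, min(init_l, n_particles))
  pop_l <- ibm_population(
    stats::rnorm(nl0, z_l, sqrt(max(config$ladybird$var_g0, 1e-12))),
    scale = if (init_l > 0) init_l / nl0 else 1)
  lady_active <- FALSE

  days <- start_day:end_day
  out <- tibble::tibble(
    day = days, A = NA_real_, L = NA_real_,
    mean_g_A = NA_real_, mean_g_L = NA_real_)
  for (i in seq_along(days)) {
    T <- temperature_at(climate, days[i])
    if (!lady_active && days[i] >= lady_day) lady_active <- TRUE
    stepped <- ibm_step(
      pop_a, if (lady_active) pop_l else ibm_population(numeric(0)),
      T, dt = config$numerics$dt, config = config, cap = n_particles)
    pop_a <- stepped$pop_a
    if (lady_active) pop_l <- stepped$pop_l
    out$A[i] <- ibm_abundance(pop_a)
    out$L[i] <- if (lady_active) ibm_abundance(pop_l) else 0
    out$mean_g_A[i] <- mean(pop_a$z_g)
    out$mean_g_L[i] <- mean(pop_l$z_g)
    if (length(pop_a$z_g) == 0) break
  }
  out
}
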