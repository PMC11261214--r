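#' Run the coupled eco-evolutionary simulation
#'
#' Daily forward-Euler integration of the aphid-ladybird system over
#' whole years. Each day of the growing season: population mean rates are
#' computed by integrating the thermal performance curves over both
#' species' breeding-value and environmental-effect distributions;
#' abundances update as `A' = A (1 + (Fbar - Bbar) dt)` and
#' `L' = L (1 + wbar_L dt)`; then selection reweights the aphid density
#' (plus its mutational convolution) and the ladybird density, and the
#' ladybird genetic state takes its Bulmer infinitesimal-model update.
#'
#' Phenology: aphids emerge from overwintering on the first day their
#' mean growth rate (at the carryover abundance, frozen genetics) exceeds
#' the configured threshold; ladybirds emerge on the first later day
#' their own criterion is met. Aphids switch to the single sexual
#' generation -- and both species enter overwintering, losing
#' `1 - overwinter_survival` of their abundance -- on the first day that
#' daylength drops below `-0.05 T + 15.67` hours while `T` is below the
#' aphid mean thermal optimum. At the switch the aphid genetic state
#' takes its annual sexual reset (segregation with inbreeding discount);
#' over winter abundances, trait means and variances are frozen.
#'
#' A species with zero segregation variance is treated as non-evolving:
#' its trait mean and variance stay exactly constant for the whole run.
#' Ladybird extinction latches once abundance falls below
#' `extinction_threshold` (deterministic densities never reach exact
#' zero); after latching the predator stays absent.
#'
#' @param config An [default_config()] list.
#' @param climate A [climate_params()] object.
#' @param years Number of 365-day years to simulate.
#' @param z_init Length-2 numeric, initial mean thermal optima
#'   `c(aphid, ladybird)` in degrees C (the locally adapted optima; see
#'   [find_local_optima()] and [local_optima()]).
#' @param start_year Calendar year of the first simulated year (day 1 of
#'   the global day index is Jan 1, 2000).
#' @param init_state Internal: a state list returned via the
#'   `final_state` attribute of a previous run, to chain phases.
#' @param record_daily If `TRUE`, attach a tibble of daily state (day,
#'   abundances, trait means/variances) as attribute `"daily"`.
#' @param latch_extinction If `FALSE` the predator extinction latch is
#'   disabled (used by the local-adaptation relaxation, where transients
#'   may pass through low abundance).
#' @return A tibble of class `evorescue_sim` with one row per year:
#'   `year`, `AAP`, `ALP` (abundance-days from the trapezoid of the daily
#'   series), `topt_A`, `topt_L` (mean breeding values at year end),
#'   `vg_A`, `vg_L`, `aphid_start`, `ladybird_start`, `switch_day`
#'   (day-of-year, `NA` when the event did not occur), `extinct_L`.
#'   Attributes: `config`, `climate`, `final_state`, and optionally
#'   `daily`.
#' @examples
#' \donttest{
#' no <- climate_location("NO")
#' sim <- run_simulation(default_config(), no, years = 3,
#'                       z_init = c(19, 18.5))
#' sim
#' }
#' @export
run_simulation <- function(config, climate, years, z_init = NULL,
                           start_year = 2000, init_state = NULL,
                           record_daily = FALSE,
                           latch_extinction = TRUE) {
  stopifnot(inherits(climate, "climate_params"), years >= 1)
  cfg <- config
  num <- cfg$numerics
  dt <- num$dt
  steps_per_day <- round(1 / dt)
  if (abs(steps_per_day * dt - 1) > 1e-9) {
    stop("`dt` must divide one day evenly")
  }
  eco <- eco_from_config(cfg)
  tpc_a <- tpc_from_config(cfg, "aphid")
  tpc_l <- tpc_from_config(cfg, "ladybird")
  dl <- daylength(climate$latitude, 1:365, p = cfg$phenology$daylength_coef)
  thr <- cfg$phenology$growth_threshold
  surv <- cfg$phenology$overwinter_survival
  ext_thr <- if (latch_extinction) num$extinction_threshold else -Inf

  day0 <- (start_year - 2000) * 365 # global day index offset

  if (is.null(init_state)) {
    if (is.null(z_init) || length(z_init) != 2) {
      stop("supply `z_init = c(aphid_optimum, ladybird_optimum)` ",
           "(see find_local_optima() / local_optima()) or an `init_state`")
    }
    gen_a <- genetic_state_from_config(cfg, "aphid", mean_g = z_init[1])
    gen_l <- genetic_state_from_config(cfg, "ladybird", mean_g = z_init[2])
    st <- list(
      A = cfg$init$A, L = cfg$init$L,
      gen_a = gen_a, gen_l = gen_l,
      dist_a = genetic_dist(gen_a, n = num$grid_n,
                            span_sd = num$grid_span_sd),
      extinct_l = FALSE,
      vg_end_prev = gen_a$var_g # reference point of the annual
                                # genetic-variance change (Eq-33 style)
    )
  } else {
    st <- init_state
  }
  evolve_a <- st$gen_a$var_g0 > 0
  evolve_l <- st$gen_l$var_g0 > 0
  if (!evolve_a) st$dist_a <- bv_dist(st$gen_a$mean_g, 1)

  # ladybird working distribution is Gaussian by construction; keep its
  # grid (and phenotype matrix) cached and rebuild density cheaply
  lady <- new.env(parent = emptyenv())
  reset_lady_grid <- function() {
    d <- genetic_dist(st$gen_l, n = num$grid_n, span_sd = num$grid_span_sd)
    lady$grid <- d$grid
    lady$dist <- d
  }
  refresh_lady_density <- function() {
    g <- lady$grid
    n <- length(g)
    if (st$gen_l$var_g == 0 || length(g) == 1) {
      lady$dist <- bv_dist(st$gen_l$mean_g, 1)
      return(invisible())
    }
    centre <- (g[1] + g[n]) / 2
    if (abs(st$gen_l$mean_g - centre) > lady$dist$dx) {
      reset_lady_grid()
    } else {
      dens <- stats::dnorm(g, st$gen_l$mean_g, sqrt(st$gen_l$var_g))
      lady$dist$density <- dens / trapz_uniform(dens, lady$dist$dx)
    }
    invisible()
  }
  reset_lady_grid()

  n_years <- as.integer(years)
  out <- vector("list", n_years)
  daily_rows <- if (record_daily) vector("list", n_years) else NULL

  for (y in seq_len(n_years)) {
    active_a <- FALSE
    active_l <- FALSE
    activated_a <- FALSE
    activated_l <- FALSE
    switched <- FALSE
    aphid_start <- NA_integer_
    lady_start <- NA_integer_
    switch_day <- NA_integer_
    a_daily <- numeric(365)
    l_daily <- numeric(365)
    if (record_daily) {
      rec <- list(mean_a = rep(NA_real_, 365), mean_l = rep(NA_real_, 365),
                  vg_a = rep(NA_real_, 365), vg_l = rep(NA_real_, 365))
    }

    for (d in 1:365) {
      t_global <- day0 + (y - 1) * 365 + d
      T <- temperature_at(climate, t_global)

      if (!switched) {
        # emergence of the prey from overwintering
        if (!active_a && !activated_a) {
          r <- mean_rates(st$dist_a, lady$dist, st$gen_a, st$gen_l, T,
                          A = st$A, L = 0, tpc_a, tpc_l, eco)
          if (r$Fbar > thr) {
            active_a <- TRUE
            activated_a <- TRUE
            aphid_start <- d
          }
        }

        if (active_a) {
          # photoperiod-temperature switch to the sexual generation;
          # evaluated only under declining daylength (after the summer
          # solstice, day 172): sexual induction is a short-day autumn
          # cue, and the same numeric condition would otherwise fire on
          # cool spring days. The switch day itself is spent entering
          # overwintering.
          if (d > 172 && dl[d] < -0.05 * T + 15.67 &&
              T < st$gen_a$mean_g) {
            switched <- TRUE
            switch_day <- d
            if (evolve_a) {
              vg_end <- bv_var(st$dist_a)
              st$gen_a <- sexual_reset_aphid(
                st$gen_a, vg_end - st$vg_end_prev, st$dist_a,
                nested = cfg$genetics$vg_reset_nested)
              st$vg_end_prev <- vg_end
              st$dist_a <- genetic_dist(st$gen_a, n = num$grid_n,
                                        span_sd = num$grid_span_sd)
            }
            st$A <- st$A * surv
            if (!st$extinct_l) st$L <- st$L * surv
            active_a <- FALSE
            active_l <- FALSE
          }
        }

        if (active_a && !switched) {
          for (sub in seq_len(steps_per_day)) {
            stepped <- sim_step_core(
              st$A, st$L, st$dist_a, lady$dist, st$gen_a, st$gen_l, T,
              dt, tpc_a, tpc_l, eco, evolve_a, evolve_l, active_l,
              num$grid_n, num$grid_span_sd)
            r <- stepped$rates
            st$A <- stepped$A
            st$dist_a <- stepped$dist_a
            st$gen_a <- stepped$gen_a
            if (active_l) {
              st$L <- stepped$L
              st$gen_l <- stepped$gen_l
              refresh_lady_density()
              if (st$L < ext_thr) {
                st$extinct_l <- TRUE
                st$L <- 0
                active_l <- FALSE
              }
            }
            if (!is.finite(st$A) || !is.finite(st$L)) {
              stop("non-finite abundance at year ", start_year + y - 1,
                   " day ", d, " (A = ", st$A, ", L = ", st$L, ")")
            }
          }

          # emergence of the predator once its own growth criterion
          # holds (wbar_l from the day's rates, which used L = 0)
          if (!active_l && !activated_l && !st$extinct_l) {
            if (r$wbar_l > thr) {
              if (st$L < num$extinction_threshold && latch_extinction) {
                st$extinct_l <- TRUE
                st$L <- 0
              } else {
                active_l <- TRUE
                activated_l <- TRUE
                lady_start <- d
              }
            }
          }
        }
      }

      a_daily[d] <- if (active_a) st$A else 0
      l_daily[d] <- if (active_l) st$L else 0
      if (record_daily) {
        rec$mean_a[d] <- st$gen_a$mean_g
        rec$mean_l[d] <- st$gen_l$mean_g
        rec$vg_a[d] <- st$gen_a$var_g
        rec$vg_l[d] <- st$gen_l$var_g
      }
    }

    # a season still open at the calendar year end (or one that never
    # opened) closes into overwintering here so the annual mortality is
    # paid exactly once per year
    if (!switched) {
      if (active_a && evolve_a) {
        vg_end <- bv_var(st$dist_a)
        st$gen_a <- sexual_reset_aphid(
          st$gen_a, vg_end - st$vg_end_prev, st$dist_a,
          nested = cfg$genetics$vg_reset_nested)
        st$vg_end_prev <- vg_end
        st$dist_a <- genetic_dist(st$gen_a, n = num$grid_n,
                                  span_sd = num$grid_span_sd)
      }
      st$A <- st$A * surv
      if (!st$extinct_l) st$L <- st$L * surv
      active_a <- FALSE
      active_l <- FALSE
    }

    out[[y]] <- tibble::tibble(
      year = as.integer(start_year + y - 1),
      AAP = trapz_uniform(a_daily, 1),
      ALP = trapz_uniform(l_daily, 1),
      topt_A = st$gen_a$mean_g,
      topt_L = st$gen_l$mean_g,
      vg_A = st$gen_a$var_g,
      vg_L = st$gen_l$var_g,
      aphid_start = aphid_start,
      ladybird_start = lady_start,
      switch_day = switch_day,
      extinct_L = st$extinct_l
    )
    if (record_daily) {
      daily_rows[[y]] <- tibble::tibble(
        year = as.integer(start_year + y - 1), day = 1:365,
        A = a_daily, L = l_daily,
        mean_g_A = rec$mean_a, mean_g_L = rec$mean_l,
        vg_A = rec$vg_a, vg_L = rec$vg_l
      )
    }
  }

  res <- dplyr::bind_rows(out)
  class(res) <- c("evorescue_sim", class(res))
  attr(res, "config") <- cfg
  attr(res, "climate") <- climate
  attr(res, "final_state") <- st
  if (record_daily) attr(res, "daily") <- dplyr::bind_rows(daily_rows)
  res
}

#' Sexual-phase switch criterion
#'
#' The photoperiod-temperature rule that flips the prey from asexual to
#' sexual reproduction (and sends both species into overwintering):
#' returns 1 when daylength (hours) is below `-0.05 T + 15.67` and the
#' temperature is below the aphid mean thermal optimum, else 0.
#'
#' @param T Temperature (degrees C).
#' @param DL Daylength (hours).
#' @param mean_z_a Aphid mean thermal optimum (degrees C).
#' @return 0 or 1 (vectorized).
#' @examples
#' sexual_switch(T = 10, DL = 12, mean_z_a = 19) # 1: short, cool day
#' sexual_switch(T = 20, DL = 12, mean_z_a = 19) # 0: too warm
#' @export
sexual_switch <- function(T, DL, mean_z_a) {
  as.integer(DL < -0.05 * T + 15.67 & T < mean_z_a)
}

#' Overwintering transition
#'
#' Applies the annual overwintering mortality (both species lose
#' `1 - survival` of their abundance), freezes genetic states, and marks
#' both species dormant. Idempotent: a state already overwintering is
#' returned unchanged.
#'
#' @param state A list with fields `A`, `L`, `phase_a`, `phase_l` (and
#'   any genetic fields, which are left untouched).
#' @param survival Overwinter survival fraction (default 0.8).
#' @return The updated state list.
#' @examples
#' st <- list(A = 1e6, L = 5000, phase_a = "active", phase_l = "active")
#' overwinter(st)$A # 800000
#' @export
overwinter <- function(state, survival = 0.8) {
  if (identical(state$phase_a, "dormant") &&
      identical(state$phase_l, "dormant")) {
    return(state)
  }
  state$A <- state$A * survival
  state$L <- state$L * survival
  state$phase_a <- "dormant"
  state$phase_l <- "dormant"
  state
}


# one coupled daily update, shared by the exported sim_step() and the
# simulation loop: mean rates -> abundance updates -> prey selection +
# mutation -> predator selection -> predator Bulmer update
sim_step_core <- function(A, L, dist_a, dist_l, gen_a, gen_l, T, dt,
                          tpc_a, tpc_l, eco, evolve_a, evolve_l,
                          active_l, grid_n = 601, grid_span_sd = 8) {
  r <- mean_rates(dist_a, dist_l, gen_a, gen_l, T,
                  A = A, L = if (active_l) L else 0, tpc_a, tpc_l, eco)
  # abundance updates (one beta evaluation shared between the prey-loss
  # and predator-recruitment terms); a growth multiplier <= 0 means the
  # whole population is lost within the step (the selection equations'
  # collapse condition)
  mult_a <- 1 + (r$Fbar - r$Bbar) * dt
  A_new <- max(A * mult_a, 0)
  L_new <- if (active_l) max(L * (1 + r$wbar_l * dt), 0) else L
  if (evolve_a && mult_a > 0) {
    dist_a <- select_aphid(dist_a, r$F_of_zg, r$Bbar, r$Fbar, dt)
    dist_a <- mutate_aphid(dist_a, gen_a$var_tau * dt)
    gen_a$mean_g <- bv_mean(dist_a)
    gen_a$var_g <- bv_var(dist_a)
    dist_a <- bv_maintain(dist_a)
  }
  if (active_l && evolve_l) {
    sel <- select_ladybird(dist_l, r$w_of_zg, r$wbar_l, dt)
    gen_l <- update_ladybird_genetics(gen_l, sel, dt)
  }
  list(A = A_new, L = L_new, dist_a = dist_a, gen_a = gen_a,
       gen_l = gen_l, rates = r)
}

#' One daily step of the coupled eco-evolutionary dynamics
#'
#' Applies, in order: population mean rates; the expected abundance
#' updates `A' = A (1 + (Fbar - Bbar) dt)` and
#' `L' = L (1 + wbar_L dt)`; prey selection and mutational convolution
#' on the tracked breeding-value density; predator selection and the
#' Bulmer infinitesimal-model update, after which the predator's
#' working distribution is the normal implied by its updated genetic
#' state. This is the same operation the simulation loop applies on
#' every active day.
#'
#' @param state A list with elements `A`, `L` (abundances), `dist_a`
#'   (aphid [bv_dist()]), `gen_a`, `gen_l` ([genetic_state()]s), and
#'   optionally `active_l` (default `TRUE`; when `FALSE` the predator
#'   is dormant and exerts no predation) and `dist_l` (defaults to the
#'   normal distribution implied by `gen_l`).
#' @param T Temperature (degrees C).
#' @param dt Time step in days.
#' @param config A [default_config()] list.
#' @return The updated state list (with a fresh `dist_l`), plus the
#'   day's mean rates in element `rates`.
#' @examples
#' gen_a <- genetic_state(20, inbreeding_f = 0.1)
#' gen_l <- genetic_state(20.3)
#' st <- list(A = 1e6, L = 5e3, dist_a = genetic_dist(gen_a),
#'            gen_a = gen_a, gen_l = gen_l)
#' sim_step(st, T = 20, dt = 1)$A
#' @export
sim_step <- function(state, T, dt = 1, config = default_config()) {
  stopifnot(is.list(state), state$A >= 0, state$L >= 0)
  active_l <- if (is.null(state$active_l)) TRUE else state$active_l
  num <- config$numerics
  dist_l <- state$dist_l
  if (is.null(dist_l)) {
    dist_l <- genetic_dist(state$gen_l, n = num$grid_n,
                           span_sd = num$grid_span_sd)
  }
  out <- sim_step_core(
    state$A, state$L, state$dist_a, dist_l, state$gen_a, state$gen_l,
    T, dt,
    tpc_from_config(config, "aphid"), tpc_from_config(config, "ladybird"),
    eco_from_config(config),
    evolve_a = state$gen_a$var_g0 > 0, evolve_l = state$gen_l$var_g0 > 0,
    active_l = active_l, grid_n = num$grid_n,
    grid_span_sd = num$grid_span_sd)
  out$dist_l <- genetic_dist(out$gen_l, n = num$grid_n,
                             span_sd = num$grid_span_sd)
  out$active_l <- active_l
  out
}
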