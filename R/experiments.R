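#' Scenario definition
#'
#' The three model scenarios, plus the factorial evolution toggles and
#' climate/genetic-variance overrides used by the manipulation
#' experiments:
#' * Model 1 -- no evolution, stable climate: the warming trend is forced
#'   to zero (the year-2000 seasonal cycle repeats) and both segregation
#'   variances are zero.
#' * Model 2 -- no evolution, with climate change: both segregation
#'   variances are zero, the trend acts.
#' * Model 3 -- full eco-evolutionary model: both species evolve (unless
#'   an `evolve_*` flag or `vg0_*` override says otherwise).
#'
#' @param model_id 1, 2 or 3.
#' @param evolve_a,evolve_l Evolution toggles for the four-way factorial
#'   (Model 3 only); `FALSE` forces that species' segregation variance to
#'   zero.
#' @param s_override,k_override Optional replacement seasonality /
#'   warming trend (for the swap and sweep experiments).
#' @param vg0_a,vg0_l Optional segregation-variance overrides
#'   (sensitivity analyses).
#' @return An object of class `evorescue_scenario`.
#' @examples
#' scenario(3)
#' scenario(3, evolve_l = FALSE)
#' @export
scenario <- function(model_id, evolve_a = TRUE, evolve_l = TRUE,
                     s_override = NULL, k_override = NULL,
                     vg0_a = NULL, vg0_l = NULL) {
  stopifnot(model_id %in% 1:3)
  if (model_id != 3 && (!evolve_a || !evolve_l || !is.null(vg0_a) ||
                        !is.null(vg0_l))) {
    stop("evolution toggles and vg0 overrides apply to Model 3 only")
  }
  structure(
    list(model_id = model_id, evolve_a = evolve_a, evolve_l = evolve_l,
         s_override = s_override, k_override = k_override,
         vg0_a = vg0_a, vg0_l = vg0_l),
    class = "evorescue_scenario"
  )
}

#' @export
print.evorescue_scenario <- function(x, ...) {
  cat(sprintf("<scenario> Model %d (evolve A: %s, L: %s)\n", x$model_id,
              x$evolve_a, x$evolve_l))
  invisible(x)
}

resolve_climate <- function(location) {
  if (inherits(location, "climate_params")) location
  else climate_location(location)
}

apply_climate_overrides <- function(climate, scen) {
  if (!is.null(scen$s_override)) climate$seasonality <- scen$s_override
  if (!is.null(scen$k_override)) climate$trend <- scen$k_override
  climate
}

#' Run a model scenario at a location
#'
#' Reproduces the computational experiment design: the full
#' eco-evolutionary dynamics are run over a flush period (calendar years
#' 2000 to 2000 + `flush_years` - 1) to replace the nominal initial
#' conditions with realistic ones, then the scenario's toggles are
#' applied and the recorded phase runs for `years - flush_years` further
#' years. Under Models 1 and 2 the genetic state inherited from the flush
#' is frozen (segregation variance zero, degenerate trait distribution at
#' the flushed mean); under Model 1 the warming trend is additionally set
#' to zero.
#'
#' @param scen A [scenario()].
#' @param location A `climate_params` object or a two-letter id from
#'   [climate_locations()].
#' @param years Total simulated years including the flush.
#' @param config A [default_config()] list.
#' @param flush_years Length of the flush period (years).
#' @param z_init Initial mean thermal optima `c(aphid, ladybird)`; by
#'   default looked up in [local_optima()] for the nine reference
#'   locations (by label), otherwise computed with
#'   [find_local_optima()].
#' @param record_daily Attach daily state as attribute `"daily"`.
#' @return A tibble of class `evorescue_sim` with the columns of
#'   [run_simulation()] plus `phase` (`"flush"` or `"scenario"`).
#' @examples
#' \donttest{
#' sim <- run_scenario(scenario(2), "NO", years = 40)
#' glance(sim)
#' }
#' @export
run_scenario <- function(scen, location, years = 151,
                         config = default_config(), flush_years = 21,
                         z_init = NULL, record_daily = FALSE) {
  stopifnot(inherits(scen, "evorescue_scenario"))
  climate <- apply_climate_overrides(resolve_climate(location), scen)
  if (years <= flush_years) stop("`years` must exceed `flush_years`")
  if (is.null(z_init)) z_init <- default_z_init(climate, config)

  # the flush runs under the full eco-evolutionary dynamics; Model 1 is
  # a stable world throughout, so its flush also sees the zero-trend
  # climate (otherwise its frozen traits would carry a spurious
  # warming-adapted offset into the stable baseline)
  flush_climate <- climate
  if (scen$model_id == 1) flush_climate$trend <- 0
  flush <- run_simulation(config, flush_climate, years = flush_years,
                          z_init = z_init, start_year = 2000,
                          record_daily = record_daily)
  st <- attr(flush, "final_state")

  cfg2 <- config
  climate2 <- climate
  if (scen$model_id == 1) {
    climate2$trend <- 0
  }
  if (scen$model_id %in% c(1, 2)) {
    st <- freeze_species(st, "a")
    st <- freeze_species(st, "l")
  } else {
    if (!scen$evolve_a || identical(scen$vg0_a, 0)) {
      st <- freeze_species(st, "a")
    } else if (!is.null(scen$vg0_a)) {
      st$gen_a$var_g0 <- scen$vg0_a
    }
    if (!scen$evolve_l || identical(scen$vg0_l, 0)) {
      st <- freeze_species(st, "l")
    } else if (!is.null(scen$vg0_l)) {
      st$gen_l$var_g0 <- scen$vg0_l
    }
  }

  rec <- run_simulation(cfg2, climate2, years = years - flush_years,
                        z_init = NULL, start_year = 2000 + flush_years,
                        init_state = st, record_daily = record_daily)

  out <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(flush), phase = "flush"),
    dplyr::mutate(tibble::as_tibble(rec), phase = "scenario")
  )
  class(out) <- c("evorescue_sim", class(out))
  attr(out, "config") <- config
  attr(out, "climate") <- climate2
  attr(out, "scenario") <- scen
  attr(out, "final_state") <- attr(rec, "final_state")
  if (record_daily) {
    attr(out, "daily") <- dplyr::bind_rows(attr(flush, "daily"),
                                           attr(rec, "daily"))
  }
  out
}

# freeze a species' evolution: degenerate distribution at the current
# mean, zero variance components
freeze_species <- function(st, which) {
  if (which == "a") {
    st$gen_a$var_g0 <- 0
    st$gen_a$var_g <- 0
    st$gen_a$dev <- 0
    st$dist_a <- bv_dist(st$gen_a$mean_g, 1)
  } else {
    st$gen_l$var_g0 <- 0
    st$gen_l$var_g <- 0
    st$gen_l$dev <- 0
  }
  st
}

# initial optima: packaged table for the nine reference locations under
# the default parameters, otherwise computed by relaxation
default_z_init <- function(climate, config) {
  opt <- local_optima()
  hit <- opt[opt$id == climate$label, ]
  if (nrow(hit) == 1 && identical(unclass(config),
                                  unclass(default_config()))) {
    return(c(hit$zstar_a, hit$zstar_l))
  }
  message("computing locally adapted optima by relaxation for '",
          climate$label, "' (use `z_init` to skip)")
  z <- find_local_optima(climate, config)
  c(z$zstar_a, z$zstar_l)
}

#' Locally adapted thermal optima at a stable climate
#'
#' Finds the pair of mean thermal optima at which the full
#' eco-evolutionary dynamics are stationary under the location's stable
#' (zero-trend) climate, by evolutionary relaxation: the coupled system
#' is run with the trend switched off (and the predator extinction latch
#' disabled, so transients may pass through low abundance) until the
#' year-over-year displacement of both trait means falls below `tol`.
#' The converged means are the locally adapted optima used as initial
#' conditions of the scenario runs.
#'
#' @param climate A `climate_params` object (the trend is ignored).
#' @param config A [default_config()] list.
#' @param z_start Optional starting guess `c(aphid, ladybird)`; defaults
#'   to a warm-season heuristic `t_mean + 0.6 * seasonality`.
#' @param max_years Relaxation horizon.
#' @param tol Convergence tolerance on the per-year trait displacement
#'   (degrees C per year).
#' @return A list with `zstar_a`, `zstar_l`, `converged`, `years_run`,
#'   `drift` (final per-year displacement, degrees C).
#' @examples
#' \donttest{
#' find_local_optima(climate_location("SO"))
#' }
#' @export
find_local_optima <- function(climate, config = default_config(),
                              z_start = NULL, max_years = 120,
                              tol = 0.01) {
  stable <- climate
  stable$trend <- 0
  # default starts near the summer peak (the selection balance sits a
  # little below it); fall back to cooler starts if a candidate basin
  # loses the predator
  starts <- if (is.null(z_start)) {
    lapply(c(0.9, 1.0, 0.75),
           function(f) rep(stable$t_mean + f * stable$seasonality, 2))
  } else {
    list(z_start)
  }
  block <- 30
  best <- NULL
  for (z0 in starts) {
    sim <- run_simulation(config, stable, years = block, z_init = z0,
                          latch_extinction = FALSE)
    years_run <- block
    repeat {
      n <- nrow(sim)
      drift <- max(abs(sim$topt_A[n] - sim$topt_A[n - 1]),
                   abs(sim$topt_L[n] - sim$topt_L[n - 1]))
      if (drift < tol || years_run >= max_years) break
      sim <- run_simulation(config, stable, years = block, z_init = NULL,
                            init_state = attr(sim, "final_state"),
                            latch_extinction = FALSE)
      years_run <- years_run + block
    }
    n <- nrow(sim)
    cand <- list(zstar_a = sim$topt_A[n], zstar_l = sim$topt_L[n],
                 converged = drift < tol, years_run = years_run,
                 drift = drift, aap = sim$AAP[n], alp = sim$ALP[n])
    if (cand$aap > 0 && cand$alp > 0) {
      return(cand[c("zstar_a", "zstar_l", "converged", "years_run",
                    "drift")])
    }
    if (is.null(best) || cand$aap + cand$alp > best$aap + best$alp) {
      best <- cand
    }
  }
  stop("no persisting optimum pair found for '", climate$label,
       "': final AAP = ", format(best$aap), ", ALP = ",
       format(best$alp), "; best candidates z_A = ",
       round(best$zstar_a, 2), ", z_L = ", round(best$zstar_l, 2))
}

#' Packaged locally adapted optima for the nine reference locations
#'
#' Mean thermal optima at stationarity under each location's stable
#' climate and the default parameters, precomputed with
#' [find_local_optima()] (tolerance 0.01 degrees C per year) and frozen
#' here so scenario runs at the reference locations need not repeat the
#' relaxation. Regenerate after changing default parameters with
#' `purrr::map(climate_locations()$id, ~ find_local_optima(climate_location(.x)))`.
#'
#' @return A tibble with columns `id`, `zstar_a`, `zstar_l`.
#' @export
local_optima <- function() {
  tibble::tribble(
    ~id,  ~zstar_a, ~zstar_l,
    "SW", 25.505,   25.891,
    "SO", 27.580,   27.959,
    "SE", 25.696,   26.071,
    "CW", 18.554,   18.941,
    "CO", 26.948,   27.266,
    "CE", 23.857,   24.208,
    "NW", 20.153,   20.448,
    "NO", 24.580,   24.842,
    "NE", 22.223,   22.496
  )
}

#' Seasonality-by-trend sweep
#'
#' One full Model-3 run per (s, k) cell at the given location, reporting
#' the final-year and last-decade ladybird abundance and the extinction
#' flag. Rows are ordered by `s` then `k`.
#'
#' @param location Location id or `climate_params`.
#' @param s_values,k_values Seasonality (degrees C) and trend (degrees C
#'   per 100 years) grids; non-empty.
#' @param years,config,flush_years Passed to [run_scenario()].
#' @return A tibble of class `evorescue_sweep`: `s`, `k`, `AAP_final`,
#'   `ALP_final`, `ALP_last_decade`, `extinct_L`.
#' @export
sweep_seasonality_trend <- function(location, s_values, k_values,
                                    years = 151,
                                    config = default_config(),
                                    flush_years = 21) {
  stopifnot(length(s_values) >= 1, length(k_values) >= 1)
  climate <- resolve_climate(location)
  grid <- tidyr::expand_grid(s = sort(s_values), k = sort(k_values))
  # locally adapted optima depend on the stable seasonal cycle only, so
  # one relaxation per seasonality value serves every trend in that row
  z_by_s <- lapply(unique(grid$s), function(s) {
    cl <- climate
    cl$seasonality <- s
    z <- find_local_optima(cl, config)
    c(z$zstar_a, z$zstar_l)
  })
  names(z_by_s) <- as.character(unique(grid$s))
  res <- purrr::pmap(grid, function(s, k) {
    sim <- run_scenario(scenario(3, s_override = s, k_override = k),
                        climate, years = years, config = config,
                        flush_years = flush_years,
                        z_init = z_by_s[[as.character(s)]])
    g <- glance(sim)
    tibble::tibble(s = s, k = k, AAP_final = g$AAP_final,
                   ALP_final = g$ALP_final,
                   ALP_last_decade = g$ALP_last_decade,
                   extinct_L = g$extinct_L)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("evorescue_sweep", class(out))
  attr(out, "climate") <- climate
  out
}

#' Climate-parameter swap experiment
#'
#' Runs Model 3 at two locations with their seasonality and/or warming
#' trend exchanged, alongside the unswapped baselines, to ask which
#' climate characteristic controls the predator's evolutionary rescue.
#'
#' @param loc_a,loc_b Location ids or `climate_params` (distinct).
#' @param which One of `"s"`, `"k"`, `"both"`: which parameter(s) to
#'   exchange.
#' @param years,config,flush_years Passed to [run_scenario()].
#' @return A tibble with one row per run: `location`, `run`
#'   (`"baseline"` or `"swapped"`), `s`, `k`, `AAP_final`, `ALP_final`,
#'   `ALP_last_decade`, `extinct_L`.
#' @export
swap_experiment <- function(loc_a, loc_b, which = c("s", "k", "both"),
                            years = 151, config = default_config(),
                            flush_years = 21) {
  which <- match.arg(which)
  ca <- resolve_climate(loc_a)
  cb <- resolve_climate(loc_b)
  if (identical(ca$label, cb$label)) stop("locations must be distinct")
  swap_s <- which %in% c("s", "both")
  swap_k <- which %in% c("k", "both")

  one <- function(base, other, run) {
    scen <- scenario(
      3,
      s_override = if (run == "swapped" && swap_s) other$seasonality,
      k_override = if (run == "swapped" && swap_k) other$trend
    )
    sim <- run_scenario(scen, base, years = years, config = config,
                        flush_years = flush_years,
                        z_init = default_z_init(base, config))
    g <- glance(sim)
    cl <- attr(sim, "climate")
    tibble::tibble(location = base$label, run = run,
                   s = cl$seasonality, k = cl$trend,
                   AAP_final = g$AAP_final, ALP_final = g$ALP_final,
                   ALP_last_decade = g$ALP_last_decade,
                   extinct_L = g$extinct_L)
  }
  dplyr::bind_rows(
    one(ca, cb, "baseline"), one(ca, cb, "swapped"),
    one(cb, ca, "baseline"), one(cb, ca, "swapped")
  )
}

#' Segregation-variance sensitivity analysis
#'
#' Model-3 runs with the segregation variance of one species overridden,
#' reporting the predator outcome and the evolved trait means.
#'
#' @param location Location id or `climate_params`.
#' @param species `"aphid"` or `"ladybird"`: whose segregation variance
#'   to vary.
#' @param vg0_values Non-negative segregation variances to try.
#' @param years,config,flush_years Passed to [run_scenario()].
#' @return A tibble: `vg0`, `AAP_final`, `ALP_final`, `ALP_last_decade`,
#'   `extinct_L`, `topt_A_final`, `topt_L_final`.
#' @export
sensitivity_vg0 <- function(location, species = c("ladybird", "aphid"),
                            vg0_values, years = 151,
                            config = default_config(),
                            flush_years = 21) {
  species <- match.arg(species)
  stopifnot(all(vg0_values >= 0))
  climate <- resolve_climate(location)
  z0 <- default_z_init(climate, config)
  res <- purrr::map(vg0_values, function(v) {
    scen <- if (species == "ladybird") scenario(3, vg0_l = v)
            else scenario(3, vg0_a = v)
    sim <- run_scenario(scen, climate, years = years, config = config,
                        flush_years = flush_years, z_init = z0)
    g <- glance(sim)
    tibble::tibble(vg0 = v, AAP_final = g$AAP_final,
                   ALP_final = g$ALP_final,
                   ALP_last_decade = g$ALP_last_decade,
                   extinct_L = g$extinct_L,
                   topt_A_final = g$topt_A_final,
                   topt_L_final = g$topt_L_final)
  })
  dplyr::bind_rows(res)
}
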