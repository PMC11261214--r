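#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an annual simulation result
#'
#' `tidy()` returns the plain annual tibble (one row per year);
#' `glance()` condenses a run to one row of headline outcomes, reporting
#' the predator abundance both at the final year and as the mean of the
#' last decade.
#'
#' @param x An `evorescue_sim` tibble from [run_simulation()] or
#'   [run_scenario()].
#' @param ... Unused.
#' @return `tidy()`: a tibble, one row per year. `glance()`: a one-row
#'   tibble with `years`, `AAP_final`, `ALP_final`, `AAP_last_decade`,
#'   `ALP_last_decade`, `extinct_L`, `extinction_year`, `topt_A_final`,
#'   `topt_L_final`, `topt_A_shift`, `topt_L_shift` (trait change over
#'   the recorded phase, degrees C).
#' @method tidy evorescue_sim
#' @export
tidy.evorescue_sim <- function(x, ...) {
  out <- tibble::as_tibble(x)
  for (a in c("config", "climate", "scenario", "final_state", "daily")) {
    attr(out, a) <- NULL
  }
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.evorescue_sim
#' @method glance evorescue_sim
#' @export
glance.evorescue_sim <- function(x, ...) {
  rec <- if ("phase" %in% names(x)) x[x$phase == "scenario", ] else x
  if (nrow(rec) == 0) rec <- x
  n <- nrow(rec)
  last10 <- rec[max(1, n - 9):n, ]
  ext_year <- if (any(rec$extinct_L)) rec$year[which(rec$extinct_L)[1]]
              else NA_integer_
  tibble::tibble(
    years = n,
    AAP_final = rec$AAP[n],
    ALP_final = rec$ALP[n],
    AAP_last_decade = mean(last10$AAP),
    ALP_last_decade = mean(last10$ALP),
    extinct_L = rec$extinct_L[n],
    extinction_year = ext_year,
    topt_A_final = rec$topt_A[n],
    topt_L_final = rec$topt_L[n],
    topt_A_shift = rec$topt_A[n] - rec$topt_A[1],
    topt_L_shift = rec$topt_L[n] - rec$topt_L[1]
  )
}

#' Plot annual population pressure over time
#'
#' Annual aphid and ladybird pressure (abundance-days) on free log-style
#' facets, with the flush period shaded when present.
#'
#' @param object An `evorescue_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evorescue_sim
#' @export
autoplot.evorescue_sim <- function(object, ...) {
  dat <- tidy(object)
  long <- tidyr::pivot_longer(
    dat[, c("year", "AAP", "ALP")], c("AAP", "ALP"),
    names_to = "species", values_to = "pressure")
  long$species <- ifelse(long$species == "AAP", "aphid (AAP)",
                         "ladybird (ALP)")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$pressure)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "year", y = "annual pressure (abundance-days)") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(dat) && any(dat$phase == "flush")) {
    flush_end <- max(dat$year[dat$phase == "flush"])
    p <- p + ggplot2::geom_vline(xintercept = flush_end + 0.5,
                                 linetype = "dashed", color = "grey50")
  }
  p
}

#' Plot evolving thermal optima over time
#'
#' @param object An `evorescue_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_topt <- function(object, ...) {
  dat <- tidy(object)
  long <- tidyr::pivot_longer(
    dat[, c("year", "topt_A", "topt_L")], c("topt_A", "topt_L"),
    names_to = "species", values_to = "topt")
  long$species <- ifelse(long$species == "topt_A", "aphid", "ladybird")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$topt,
                                     color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "mean thermal optimum (\u00b0C)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a seasonality-by-trend sweep
#'
#' Tile map of final predator pressure across the (s, k) grid, with
#' extinct cells marked.
#'
#' @param object An `evorescue_sweep` tibble from
#'   [sweep_seasonality_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evorescue_sweep
#' @export
autoplot.evorescue_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s, .data$k,
                                       fill = .data$ALP_final)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object[object$extinct_L, ],
                        shape = 4, color = "red") +
    ggplot2::labs(x = "seasonality s (\u00b0C)",
                  y = "trend k (\u00b0C / 100 yr)",
                  fill = "final ALP") +
    ggplot2::theme_minimal()
}

#' Write an annual summary as CSV
#'
#' Deterministic row order (by year), six-decimal fixed formatting for
#' the continuous columns.
#'
#' @param sim An `evorescue_sim` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_annual_csv <- function(sim, path) {
  dat <- tidy(sim)
  dat <- dat[order(dat$year), ]
  fmt <- function(v) sprintf("%.6f", v)
  int_or_na <- function(v) ifelse(is.na(v), "NA", as.character(v))
  lines <- c(
    "year,AAP,ALP,topt_A,topt_L,vg_A,vg_L,aphid_start,ladybird_start,switch_day,extinct_L",
    sprintf("%d,%s,%s,%s,%s,%s,%s,%s,%s,%s,%s",
            dat$year, fmt(dat$AAP), fmt(dat$ALP), fmt(dat$topt_A),
            fmt(dat$topt_L), fmt(dat$vg_A), fmt(dat$vg_L),
            int_or_na(dat$aphid_start), int_or_na(dat$ladybird_start),
            int_or_na(dat$switch_day), ifelse(dat$extinct_L, "TRUE",
                                              "FALSE"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' Records the configuration, climate parameters and package version of
#' a run for provenance.
#'
#' @param sim An `evorescue_sim` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(sim, path) {
  cl <- attr(sim, "climate")
  manifest <- list(
    package = "evorescue",
    version = as.character(utils::packageVersion("evorescue")),
    climate = cl[c("label", "latitude", "t_mean", "seasonality", "trend")],
    config = unclass(attr(sim, "config"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
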