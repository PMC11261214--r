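#' Default run configuration
#'
#' All tunable parameters of the simulator in one nested list. Every
#' value can be overridden by `...` (using nested lists that are merged
#' into the defaults) or by editing the returned list.
#'
#' Sections:
#' * `aphid`, `ladybird`: TPC offsets `delta_min`/`delta_max` (degrees C),
#'   `peak_birth` (aphid birth at the optimum, per day), mortality
#'   baseline `m0` and rise `m1` (per day), and the genetic block
#'   `var_g0`, `var_e` (squared degrees C), `h2m`, `eta` (generations per
#'   day), `inbreeding_f`.
#' * `ecology`: searching rate `a`, handling time `h` (days), prey per
#'   predator egg `qp`, carrying capacity `K`.
#' * `init`: initial abundances `A`, `L`.
#' * `phenology`: `growth_threshold` (the per-day growth rate a dormant
#'   species must exceed to emerge: 0 = any positive growth, 1 = growth
#'   rate above one per day), `daylength_coef`
#'   (horizon coefficient of the photoperiod model, degrees),
#'   `overwinter_survival` (fraction surviving the winter).
#' * `numerics`: time step `dt` (days), breeding-value grid size `grid_n`
#'   and half-width `grid_span_sd` (in sd), predator
#'   `extinction_threshold` (abundance below which extinction latches).
#' * `genetics`: `vg_reset_nested`, the parenthesization flag of the
#'   aphid annual variance restoration (see [sexual_reset_aphid()]).
#'
#' @param ... Named overrides merged into the defaults, e.g.
#'   `default_config(ladybird = list(var_g0 = 0.6))`.
#' @return A nested list of class `evorescue_config`.
#' @examples
#' cfg <- default_config(ecology = list(qp = 400))
#' cfg$ecology$qp
#' @export
default_config <- function(...) {
  cfg <- list(
    aphid = list(
      delta_min = 18, delta_max = 6, peak_birth = 0.3,
      m0 = 0.02, m1 = 0.2,
      var_g0 = 0.3, var_e = 0.7, h2m = 1e-3, eta = 1 / 7,
      inbreeding_f = 0.1
    ),
    ladybird = list(
      delta_min = 18, delta_max = 6,
      m0 = 0.01, m1 = 0.1,
      var_g0 = 0.3, var_e = 0.7, h2m = 1e-3, eta = 1 / 7,
      inbreeding_f = 0
    ),
    ecology = list(a = 1e-7, h = 0.02, qp = 50, K = 5e7),
    init = list(A = 1e6, L = 5000),
    phenology = list(growth_threshold = 0, daylength_coef = 0.8333,
                     overwinter_survival = 0.8),
    numerics = list(dt = 1, grid_n = 601, grid_span_sd = 8,
                    extinction_threshold = 1),
    genetics = list(vg_reset_nested = FALSE)
  )
  overrides <- list(...)
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "evorescue_config")
}

# recursive merge of override lists into defaults; unknown keys rejected
merge_config <- function(base, overrides, path = "") {
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) {
      stop("unknown config key '", paste0(path, nm), "'")
    }
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]],
                                 paste0(path, nm, "$"))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

# TPC / ecology objects implied by a config
tpc_from_config <- function(cfg, species) {
  p <- cfg[[species]]
  peak <- if (species == "aphid") p$peak_birth else 0
  tpc_params(delta_min = p$delta_min, delta_max = p$delta_max,
             peak_rate = peak, m0 = p$m0, m1 = p$m1)
}

eco_from_config <- function(cfg) {
  do.call(eco_params, cfg$ecology)
}

genetic_state_from_config <- function(cfg, species, mean_g,
                                      var_g0 = NULL) {
  p <- cfg[[species]]
  if (is.null(var_g0)) var_g0 <- p$var_g0
  genetic_state(mean_g = mean_g, var_g0 = var_g0, var_e = p$var_e,
                h2m = p$h2m, eta = p$eta, inbreeding_f = p$inbreeding_f)
}

#' Read / write a run configuration as YAML
#'
#' The file mirrors the nested structure of [default_config()]; missing
#' keys keep their defaults, unknown keys are an error.
#'
#' @param path File path.
#' @param config An `evorescue_config` list.
#' @return `read_config()` returns an `evorescue_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  do.call(default_config, overrides)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
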