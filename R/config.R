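#' Reactor run configuration
#'
#' Builds the nested run configuration with nominal defaults: an
#' industrial-scale column (25 m tall, 5 m^2 cross-section, 125 m^3),
#' superficial gas velocity 75 m/h, liquid velocity 0.25 m/h (100 h liquid
#' residence time), axial dispersion 0.25 m^2/h, a CO-rich feed
#' (60 % CO / 40 % H2), nominal uptake kinetics and gas-transfer physics,
#' and a newly inoculated initial state (0.1 g/L biomass, liquid saturated
#' with the feed gases, no products).  The gas volume fraction is always
#' computed from the holdup correlation, never set directly.
#'
#' @param ... nested overrides, e.g. `geometry = list(u_G = 300)`.
#' @return A validated list of class `syncol_config`.
#' @examples
#' cfg <- run_config(feed = list(x = c(co = 0.5, h2 = 0.5, co2 = 0)))
#' cfg$geometry$u_G
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- config_defaults()
  cfg <- merge_config(cfg, user, path = character(0))
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    model = list(source = NULL, format = "auto", role_patterns = list()),
    kinetics = list(
      v_max = c(co = 35, h2 = 70, co2 = 35),
      K_m = c(co = 0.02, h2 = 0.02, co2 = 0.02),
      K_I = 10, K_I_C = 1e6, K_I_H = 1e6,
      co_inhibition = FALSE),
    gas = list(
      henry = c(co = 8e-4, h2 = 6.6e-4, co2 = 2.5e-2),
      k_m = c(co = 80, h2 = 200, co2 = 80),
      temperature = 310.15, P_top = 1.013e5,
      rho_L = 1000, g = 9.81,
      eps_G_max = 0.53, K_G = 540,
      henry_convention = "gas_concentration"),
    geometry = list(L = 25, area = 5, u_G = 75, u_L = 0.25, D_A = 0.25),
    feed = list(x = c(co = 0.6, h2 = 0.4, co2 = 0)),
    initial = list(X0 = 0.1, E0 = 0, A0 = 0),
    settings = list(t_final = 1000, N = 100, rtol = 1e-6, atol = 1e-8,
                    steady_tol = 1e-3, snapshot_dt = 50, seed = NULL,
                    scheme = "third-order-upwind"),
    recycle = list(alpha = 0)
  )
}

# Recursive merge of user overrides into the defaults; unknown keys are an
# error so typos (and attempts to set derived quantities such as eps_G)
# are caught instead of silently ignored.
merge_config <- function(base, user, path) {
  if (!is.list(user)) {
    return(coerce_leaf(base, user, path))
  }
  if (!is.list(base)) {
    # leaf in defaults that arrives as a list (e.g. named vector from YAML)
    return(coerce_leaf(base, user, path))
  }
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    where <- if (length(path)) paste0(paste(path, collapse = "$"), "$") else ""
    abort(paste0("unknown configuration key(s): ",
                 paste0(where, unknown, collapse = ", ")),
          class = "syncol_config_error")
  }
  for (nm in names(user))
    base[nm] <- list(merge_config(base[[nm]], user[[nm]], c(path, nm)))
  base
}

coerce_leaf <- function(base, value, path) {
  if (is.numeric(base) && length(base) > 1 && !is.null(names(base))) {
    v <- unlist(value)
    unknown <- setdiff(names(v), names(base))
    if (length(unknown))
      abort(paste0("unknown configuration key(s): ",
                   paste(path, collapse = "$"), "$",
                   paste(unknown, collapse = ", ")),
            class = "syncol_config_error")
    base[names(v)] <- as.numeric(v)
    return(base)
  }
  if (is.null(base)) return(value)
  if (is.logical(base)) return(as.logical(unlist(value)))
  if (is.numeric(base)) return(as.numeric(unlist(value)))
  value
}

validate_config <- function(cfg) {
  x <- cfg$feed$x
  if (any(x < 0) || abs(sum(x) - 1) > 1e-12)
    abort(sprintf("feed mole fractions must sum to 1 (got %.15g)", sum(x)),
          class = "syncol_config_error")
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  s <- cfg$settings
  chk(s$t_final > 0, "settings$t_final must be > 0")
  chk(s$N >= 5, "settings$N must be >= 5")
  chk(s$rtol > 0 && s$atol > 0, "integrator tolerances must be > 0")
  chk(s$steady_tol > 0, "settings$steady_tol must be > 0")
  g <- cfg$geometry
  chk(all(c(g$L, g$area, g$D_A) > 0) && g$u_G >= 0 && g$u_L >= 0,
      "geometry values must be positive (velocities nonnegative)")
  k <- cfg$kinetics
  chk(all(c(k$v_max, k$K_m, k$K_I, k$K_I_C, k$K_I_H) > 0),
      "kinetic constants must be positive")
  chk(cfg$recycle$alpha >= 0 && cfg$recycle$alpha < 1,
      "recycle$alpha must lie in [0, 1)")
  chk(cfg$gas$henry_convention %in% c("gas_concentration", "local_pressure"),
      "gas$henry_convention must be 'gas_concentration' or 'local_pressure'")
  chk(cfg$initial$X0 >= 0 && cfg$initial$E0 >= 0 && cfg$initial$A0 >= 0,
      "initial concentrations must be nonnegative")
  if (length(problems))
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "syncol_config_error")
  structure(cfg, class = "syncol_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Missing fields take their nominal defaults; unknown keys raise an
#' itemized error.  An empty file yields the full default configuration.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated `syncol_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path),
          class = "syncol_config_error")
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user, character(0))
  validate_config(cfg)
}

#' Write a run configuration to YAML
#'
#' @param config a `syncol_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become maps, not bare sequences
  prep <- function(x) {
    if (is.list(x)) return(lapply(x, prep))
    if (is.atomic(x) && length(x) > 1 && !is.null(names(x)))
      return(as.list(x))
    x
  }
  yaml::write_yaml(prep(unclass(config)), path)
  invisible(path)
}

# Quantities derived from the configuration: volume fractions (holdup
# correlation evaluated once at the feed superficial gas velocity and held
# constant), feed gas concentrations at bottom-of-column pressure, and the
# saturated initial dissolved concentrations.
config_derived <- function(cfg) {
  gas <- do.call(gas_physical_params,
                 cfg$gas[setdiff(names(cfg$gas), "henry_convention")])
  eps_G <- gas_holdup(cfg$geometry$u_G, gas)
  feed <- feed_gas_concentrations(cfg$feed$x, cfg$geometry, gas)
  sat0 <- vapply(c("co", "h2", "co2"), function(sp)
    saturation_concentration(feed[[sp]], gas$henry[[sp]], gas$temperature),
    numeric(1))
  kin <- do.call(uptake_kinetics, cfg$kinetics)
  list(gas = gas, kinetics = kin, eps_G = eps_G, eps_L = 1 - eps_G,
       feed_conc = feed, sat0 = sat0)
}

# Resolve the network named by the configuration (NULL -> toy fixture).
config_network <- function(cfg) {
  if (is.null(cfg$model$source)) return(toy_wlp_network())
  load_metabolic_model(cfg$model$source, cfg$model$format,
                       unlist(cfg$model$role_patterns) %||% character(0))
}

# Set a nested configuration entry by dotted path, e.g. "geometry.u_G" or
# "kinetics.v_max.h2" (the last key may index into a named vector).
config_set <- function(cfg, param, value) {
  keys <- strsplit(param, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    ok <- (is.list(node) && k %in% names(node)) ||
      (is.numeric(node) && k %in% names(node))
    if (!ok)
      abort(paste0("unknown parameter path: ", param),
            class = "syncol_config_error")
    node <- node[[k]]
  }
  cfg[[keys]] <- value
  validate_config(cfg)
}
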