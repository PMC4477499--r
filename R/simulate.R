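#' Initial column state
#'
#' The newly inoculated reactor: uniform biomass `X0`, liquid saturated
#' with the feed gases (Henry's law at the feed gas concentrations), no
#' products, gas phase equal to the feed everywhere.
#'
#' @param config a [run_config()].
#' @param network a `syncol_network` (defaults to the model named in the
#'   configuration, or the toy fixture).
#' @return Numeric matrix `N x 9` with the standard field columns.
#' @export
initial_column_state <- function(config, network = NULL) {
  eng <- build_column_engine(network %||% config_network(config), config)
  engine_initial_state(eng)
}

engine_initial_state <- function(eng) {
  N <- eng$grid$N
  cfg <- eng$config
  sat <- engine_saturation(eng, rep(eng$feed[["co"]], N),
                           rep(eng$feed[["h2"]], N),
                           rep(eng$feed[["co2"]], N))
  m <- cbind(X = rep(cfg$initial$X0, N),
             C_L = sat$co, H_L = sat$h2, D_L = sat$co2,
             E_L = rep(cfg$initial$E0, N), A_L = rep(cfg$initial$A0, N),
             C_G = rep(eng$feed[["co"]], N),
             H_G = rep(eng$feed[["h2"]], N),
             D_G = rep(eng$feed[["co2"]], N))
  m
}

#' Simulate bubble column startup
#'
#' Integrates the discretized column model from the newly inoculated
#' initial state to `settings$t_final` (default 1000 h) with a stiff
#' solver (`deSolve::lsodar`, banded Jacobian).  Every right-hand-side
#' evaluation solves one lexicographic flux-balance LP per node.
#' Integration stops early when the max-norm of the state derivative
#' falls below `settings$steady_tol`; the returned object is flagged
#' `steady` when that threshold was reached by the final time.
#'
#' @param config a [run_config()].
#' @param network a `syncol_network`; defaults to the model named in the
#'   configuration (toy fixture when none is named).
#' @param times output snapshot times (h); default
#'   `seq(0, t_final, by = settings$snapshot_dt)`.
#' @param feed_conc optional effective inlet gas concentrations (mmol/L),
#'   used by the gas-recycle driver; defaults to the fresh feed.
#' @return A `syncol_result` list: `times`, `states` (list of `N x 9`
#'   matrices), `final_state`, `steady` flag, `rhs_norm` at the final
#'   state, the effective `feed` concentrations, `config`, and solver
#'   diagnostics.
#' @export
simulate_startup <- function(config = run_config(), network = NULL,
                             times = NULL, feed_conc = NULL) {
  network <- network %||% config_network(config)
  eng <- build_column_engine(network, config, feed_conc = feed_conc)
  s <- config$settings
  if (!is.null(s$seed)) set.seed(s$seed)  # model is deterministic; recorded
  if (is.null(times))
    times <- unique(c(seq(0, s$t_final, by = s$snapshot_dt), s$t_final))
  times <- sort(unique(times))
  y0 <- as.vector(t(engine_initial_state(eng)))
  func <- function(t, y, parms) engine_rhs(t, y, eng)
  jacf <- function(t, y, parms) engine_jac(t, y, eng)
  # integrate in chunks so the approach to steady state can be checked
  # (and the run stopped) without a root function doubling the work
  n_chunks <- min(6L, length(times) - 1L)
  splits <- unique(round(seq(1L, length(times), length.out = n_chunks + 1L)))
  tt <- times[1]
  ys <- matrix(y0, nrow = 1L)
  y <- y0
  rhs_norm <- max(abs(engine_rhs(times[1], y, eng)[[1]])) # nolint
  for (ci in seq_len(length(splits) - 1L)) {
    tseg <- times[splits[ci]:splits[ci + 1L]]
    sol <- tryCatch(
      deSolve::lsoda(y = y, times = tseg, func = func, parms = NULL,
                     rtol = s$rtol, atol = s$atol,
                     jactype = "bandusr", jacfunc = jacf,
                     bandup = 17L, banddown = 26L, maxsteps = 100000L),
      error = function(e)
        abort(sprintf("integrator failure near t = %.4g h: %s",
                      tt[length(tt)], conditionMessage(e)),
              class = "syncol_numerical_error"))
    tt <- c(tt, sol[-1, 1])
    ys <- rbind(ys, sol[-1, -1, drop = FALSE])
    y <- ys[nrow(ys), ]
    rhs_norm <- max(abs(engine_rhs(tt[length(tt)], y, eng)[[1]]))
    if (rhs_norm < s$steady_tol) break
  }
  nfin <- nrow(ys)
  steady <- rhs_norm < s$steady_tol
  states <- lapply(seq_len(nfin), function(i) state_to_matrix(ys[i, ], eng$grid$N))
  structure(
    list(times = tt[seq_len(nfin)], states = states,
         final_state = states[[nfin]], final_time = tt[nfin],
         steady = steady, rhs_norm = rhs_norm,
         feed = eng$feed, z = eng$grid$z,
         config = config, network = network,
         lp_starving_nodes = sum(lex_fba_batch(
           network,
           engine_uptake_bounds(eng,
                                pmax(states[[nfin]][, "C_L"], 0),
                                pmax(states[[nfin]][, "H_L"], 0),
                                pmax(states[[nfin]][, "D_L"], 0),
                                pmax(states[[nfin]][, "E_L"], 0),
                                pmax(states[[nfin]][, "A_L"], 0)),
           eng$objectives)$status != 0L)),
    class = "syncol_result")
}

#' @export
print.syncol_result <- function(x, ...) {
  cat(sprintf("<syncol_result> %d snapshots to t = %.1f h (%s, |rhs| = %.3g)\n",
              length(x$times), x$final_time,
              if (x$steady) "steady" else "not steady", x$rhs_norm))
  invisible(x)
}

#' Steady-state reactor performance metrics
#'
#' Exit (top-of-column) titers and concentrations, the ethanol/acetate
#' mass ratio, and the CO and H2 conversions
#' `1 - G(L) / G_feed` measured on the gas phase.  The ratio is reported
#' as `Inf` when the acetate titer is below 1e-6 g/L.
#'
#' @param result a `syncol_result`.
#' @return One-row tibble of class `syncol_metrics`.
#' @export
steady_state_metrics <- function(result) {
  fs <- result$final_state
  N <- nrow(fs)
  exit <- fs[N, ]
  feed <- result$feed
  conv <- function(gout, gin) if (gin > 0) 1 - gout / gin else NA_real_
  ac <- exit[["A_L"]]
  ratio <- if (ac < 1e-6) Inf else exit[["E_L"]] / ac
  out <- tibble(
    X_gL = exit[["X"]], etoh_gL = exit[["E_L"]], ac_gL = exit[["A_L"]],
    co_L_mM = exit[["C_L"]], h2_L_mM = exit[["H_L"]], co2_L_mM = exit[["D_L"]],
    co_G_mM = exit[["C_G"]], h2_G_mM = exit[["H_G"]], co2_G_mM = exit[["D_G"]],
    ethanol_acetate_ratio = ratio,
    co_conversion = conv(exit[["C_G"]], feed[["co"]]),
    h2_conversion = conv(exit[["H_G"]], feed[["h2"]]),
    steady = result$steady)
  class(out) <- c("syncol_metrics", class(out))
  out
}

#' @export
glance.syncol_result <- function(x, ...) steady_state_metrics(x)

#' Effective inlet gas composition under partial gas recycle
#'
#' Mixes a fraction `alpha` of the column exit gas into the fresh syngas
#' feed at fixed total inlet molar concentration: the inlet mole fractions
#' are `(1 - alpha) x_fresh + alpha x_exit` and the total molar
#' concentration remains that of the fresh feed, so recycle changes the
#' inlet composition but not the gas flow.
#'
#' @param fresh named fresh-feed gas concentrations (mmol/L).
#' @param exit named exit gas concentrations (mmol/L).
#' @param alpha recycle fraction in `[0, 1)`.
#' @return Named effective inlet concentrations (mmol/L).
#' @export
apply_gas_recycle <- function(fresh, exit, alpha) {
  if (alpha < 0 || alpha >= 1)
    abort("recycle fraction must lie in [0, 1)",
          class = "syncol_config_error")
  total_fresh <- sum(fresh)
  total_exit <- sum(exit)
  x_fresh <- fresh / total_fresh
  x_exit <- if (total_exit > 0) exit / total_exit else x_fresh
  x_eff <- (1 - alpha) * x_fresh + alpha * x_exit
  x_eff * total_fresh
}

#' Simulate startup with gas recycle
#'
#' Outer fixed-point iteration over the effective inlet composition:
#' simulate, recompute the inlet from the exit gas via
#' [apply_gas_recycle()], repeat until the inlet composition changes by
#' less than `tol` (relative, default 1e-4) or `max_passes` is reached.
#'
#' @param config a [run_config()] with `recycle$alpha > 0`.
#' @param network optional `syncol_network`.
#' @param tol relative convergence tolerance on the inlet concentrations.
#' @param max_passes maximum outer iterations.
#' @return A `syncol_result` with extra elements `recycle_passes` and
#'   `recycle_converged`.
#' @export
simulate_with_recycle <- function(config = run_config(), network = NULL,
                                  tol = 1e-4, max_passes = 50) {
  network <- network %||% config_network(config)
  alpha <- config$recycle$alpha
  fresh <- config_derived(config)$feed_conc
  inlet <- fresh
  res <- NULL
  converged <- FALSE
  passes <- 0
  for (i in seq_len(max_passes)) {
    passes <- i
    res <- simulate_startup(config, network, feed_conc = inlet)
    exit_gas <- res$final_state[nrow(res$final_state),
                                c("C_G", "H_G", "D_G")]
    names(exit_gas) <- c("co", "h2", "co2")
    new_inlet <- apply_gas_recycle(fresh, exit_gas, alpha)
    rel <- max(abs(new_inlet - inlet)) / max(sum(fresh), 1e-12)
    inlet <- new_inlet
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged && alpha > 0)
    warning(sprintf("gas-recycle fixed point not converged in %d passes",
                    max_passes))
  res$recycle_passes <- passes
  res$recycle_converged <- converged
  res
}

#' Steady-state parameter sweep
#'
#' Runs one full startup simulation per parameter value and tabulates the
#' steady-state metrics.  Failed simulations are recorded as failed rows
#' and the sweep continues.
#'
#' @param config base [run_config()].
#' @param param dotted path into the configuration,
#'   e.g. `"geometry.u_G"` or `"kinetics.v_max.h2"`.
#' @param values numeric vector of parameter values.
#' @param network optional `syncol_network` reused across runs.
#' @return A tibble of class `syncol_sweep`: `value`, the metric columns,
#'   and `error` (`NA` for successful rows).
#' @export
run_parameter_sweep <- function(config, param, values, network = NULL) {
  if (any(!is.finite(values)))
    abort("sweep values must be finite", class = "syncol_config_error")
  network <- network %||% config_network(config)
  rows <- purrr::map(values, function(v) {
    out <- tryCatch({
      cfg <- config_set(config, param, v)
      res <- if (cfg$recycle$alpha > 0)
        simulate_with_recycle(cfg, network)
      else simulate_startup(cfg, network)
      m <- steady_state_metrics(res)
      m$error <- NA_character_
      m
    }, error = function(e) {
      tibble(error = conditionMessage(e))
    })
    out$value <- v
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "value")
  attr(out, "param") <- param
  class(out) <- c("syncol_sweep", class(out))
  out
}

#' Linear interpolation of a sweep response
#'
#' Trend curves are generated by linearly interpolating the simulated
#' cases, matching how sparse sweep results are usually plotted.
#'
#' @param sweep a [run_parameter_sweep()] result.
#' @param response metric column name.
#' @param n number of interpolation points.
#' @return Tibble with `value` and the interpolated response.
#' @export
interpolate_sweep <- function(sweep, response, n = 101) {
  ok <- is.na(sweep$error)
  xy <- stats::approx(sweep$value[ok], sweep[[response]][ok], n = n)
  out <- tibble(value = xy$x)
  out[[response]] <- xy$y
  out
}
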