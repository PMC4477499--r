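#' Lexicographic objective sequence
#'
#' The ordered objectives solved at every node.  The default order follows
#' the column model's convention: maximize growth, maximize CO uptake,
#' maximize H2 uptake, then minimize CO2, acetate, and ethanol synthesis.
#' Fixing each optimum before the next solve makes the reported exchange
#' fluxes unique, which is what allows the surrounding ODE system to be
#' integrated at all.
#'
#' @param order character vector of roles drawn from
#'   `c("growth", "co", "h2", "co2", "acetate", "ethanol")`.  Roles
#'   `growth`, `co` and `h2` are maximized (growth rate, uptake rates);
#'   the remaining roles are synthesis rates and are minimized.
#' @return A tibble with columns `role` and `sense` of class
#'   `syncol_objectives`.
#' @export
lexicographic_objectives <- function(order = c("growth", "co", "h2",
                                               "co2", "acetate", "ethanol")) {
  allowed <- c("growth", "co", "h2", "co2", "acetate", "ethanol")
  if (!all(order %in% allowed))
    abort("unknown objective role(s)", class = "syncol_config_error")
  sense <- ifelse(order %in% c("growth", "co", "h2"), "maximize", "minimize")
  structure(tibble(role = order, sense = sense),
            class = c("syncol_objectives", "tbl_df", "tbl", "data.frame"))
}

# Map objective roles to (column index, signed sense) for the LP core
# (+1 maximize the signed flux, -1 minimize it).  Uptake rates are positive
# magnitudes of negative exchange fluxes, so "maximize CO uptake" is
# "minimize the signed CO exchange flux"; synthesis rates are the signed
# fluxes themselves.
objective_index <- function(network, objectives) {
  cols <- match(network$exchange[objectives$role], network$reactions)
  signed_sense <- ifelse(objectives$sense == "maximize", 1L, -1L)
  uptake <- objectives$role %in% c("co", "h2")
  signed_sense[uptake] <- -signed_sense[uptake]
  list(idx = as.integer(cols), sense = as.integer(signed_sense))
}

network_dense_S <- function(network) {
  d <- attr(network, "dense_S")
  if (is.null(d)) d <- as.matrix(network$S)
  d
}

#' Solve the lexicographic flux-balance problem
#'
#' Solves the ordered sequence of linear programs over the steady-state
#' flux cone `S v = 0` with flux bounds, constraining each objective to its
#' optimum (two-sided, within `fix_tolerance`) before optimizing the next.
#' Uptake bounds are positive magnitudes applied as lower bounds
#' `-uptake_bounds[i]` on the corresponding exchange reactions, so a
#' negative returned exchange flux is consumption.
#'
#' When the maintenance-constrained problem is infeasible (gas uptake too
#' small to meet the mandatory ATP demand) the cell is treated as
#' starving: the achievable maintenance flux (capped at the demand) is
#' maximized first and growth is zero, so cells that cannot cover
#' maintenance generate no growth but keep scavenging what gas they can.
#' This keeps the flux response continuous across the growth/no-growth
#' boundary, which matters for the stiff integrator driving the column
#' model; with zero uptake bounds the starving solution is identically
#' zero.
#'
#' @param network a `syncol_network`.
#' @param uptake_bounds named nonnegative vector of maximum uptake
#'   magnitudes (mmol/gDW/h) for any subset of roles `co`, `h2`, `co2`.
#' @param objectives a [lexicographic_objectives()] tibble.
#' @param fix_tolerance relative tolerance used to fix each optimum
#'   (absolute `1e-12` floor near zero).
#' @return A `syncol_flux` list with elements `mu` (1/h), `v_co`, `v_h2`,
#'   `v_co2`, `v_etoh`, `v_ac` (mmol/gDW/h, signed), `status`
#'   (`"optimal"` or `"starving"`), and `fluxes` (the full named flux
#'   vector).
#' @examples
#' net <- toy_wlp_network()
#' sol <- solve_lexicographic_fba(net, c(co = 35, h2 = 70, co2 = 0))
#' sol$v_etoh > sol$v_ac  # H2-rich feed favours ethanol
#' @export
solve_lexicographic_fba <- function(network, uptake_bounds,
                                    objectives = lexicographic_objectives(),
                                    fix_tolerance = 1e-9) {
  stopifnot(inherits(network, "syncol_network"))
  if (any(uptake_bounds < 0))
    abort("uptake bounds must be nonnegative", class = "syncol_domain_error")
  lower <- network$lower
  upper <- network$upper
  for (role in names(uptake_bounds)) {
    rid <- network$exchange[[role]]
    lower[[rid]] <- -uptake_bounds[[role]]
    if (upper[[rid]] < lower[[rid]]) upper[[rid]] <- lower[[rid]]
  }
  obj <- objective_index(network, objectives)
  atpm <- match(network$exchange[["atp_maintenance"]], network$reactions)
  res <- .lex_fba_cpp(network_dense_S(network), unname(lower), unname(upper),
                      obj$idx, obj$sense,
                      atpm_idx = as.integer(atpm),
                      atpm_demand = unname(network$lower[[
                        network$exchange[["atp_maintenance"]]]]),
                      fix_rtol = fix_tolerance, fix_atol = 1e-12)
  as_flux_solution(res, network)
}

as_flux_solution <- function(res, network) {
  ex <- network$exchange
  ridx <- function(role) match(ex[[role]], network$reactions)
  if (res$status %in% c(0L, 2L)) {
    v <- stats::setNames(res$x, network$reactions)
    out <- list(mu = unname(v[ridx("growth")]),
                v_co = unname(v[ridx("co")]),
                v_h2 = unname(v[ridx("h2")]),
                v_co2 = unname(v[ridx("co2")]),
                v_etoh = unname(v[ridx("ethanol")]),
                v_ac = unname(v[ridx("acetate")]),
                status = if (res$status == 0L) "optimal" else "starving",
                fluxes = v)
    if (res$status == 2L) out$mu <- 0
  } else if (res$status == 1) {
    out <- list(mu = 0, v_co = 0, v_h2 = 0, v_co2 = 0, v_etoh = 0,
                v_ac = 0, status = "infeasible-as-zero", fluxes = NULL)
  } else {
    abort("LP solver failed to converge (model error: check bounds)",
          class = "syncol_model_error")
  }
  structure(out, class = "syncol_flux")
}

#' @export
print.syncol_flux <- function(x, ...) {
  cat(sprintf(paste0("<syncol_flux> %s: mu = %.4g 1/h | v_CO = %.4g, ",
                     "v_H2 = %.4g, v_CO2 = %.4g, v_EtOH = %.4g, ",
                     "v_Ac = %.4g mmol/gDW/h\n"),
              x$status, x$mu, x$v_co, x$v_h2, x$v_co2, x$v_etoh, x$v_ac))
  invisible(x)
}

#' @rdname solve_lexicographic_fba
#' @param x a `syncol_flux` object.
#' @param ... unused.
#' @export
tidy.syncol_flux <- function(x, ...) {
  tibble(role = c("growth", "co", "h2", "co2", "ethanol", "acetate"),
         flux = c(x$mu, x$v_co, x$v_h2, x$v_co2, x$v_etoh, x$v_ac),
         status = x$status)
}

# Batched per-node lexicographic solve used by the transport RHS: one call
# per RHS evaluation, row i of `uptake` holding the (co, h2, co2) bounds of
# node i.  Returns a list with `status` (integer per node) and `flux`
# (N x 6 matrix: mu, v_co, v_h2, v_co2, v_etoh, v_ac).
lex_fba_batch <- function(network, uptake, objectives, fix_tolerance = 1e-9) {
  obj <- objective_index(network, objectives)
  ex_idx <- match(network$exchange[c("co", "h2", "co2")], network$reactions)
  out_idx <- match(network$exchange[c("growth", "co", "h2", "co2",
                                      "ethanol", "acetate")],
                   network$reactions)
  atpm <- match(network$exchange[["atp_maintenance"]], network$reactions)
  res <- .lex_fba_batch_cpp(network_dense_S(network),
                            unname(network$lower), unname(network$upper),
                            as.integer(ex_idx), uptake,
                            obj$idx, obj$sense, as.integer(out_idx),
                            atpm_idx = as.integer(atpm),
                            atpm_demand = unname(network$lower[[
                              network$exchange[["atp_maintenance"]]]]),
                            fix_rtol = fix_tolerance, fix_atol = 1e-12)
  if (any(res$status > 2))
    abort("LP solver failed to converge in batched solve",
          class = "syncol_model_error")
  colnames(res$flux) <- c("mu", "v_co", "v_h2", "v_co2", "v_etoh", "v_ac")
  res
}
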