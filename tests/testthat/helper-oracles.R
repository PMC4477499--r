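# Frozen expected lexicographic flux solutions for the toy Wood-Ljungdahl
# network.  Values were computed independently with an external
# constraint-based modelling toolchain (and verified by hand from the
# fixture's balance equations) before the solver was built.
lex_oracle <- list(
  h2_rich = list(bounds = c(co = 35, h2 = 70, co2 = 0),
                 mu = 0.775, v_co = -35, v_h2 = -45.85, v_co2 = 0,
                 v_etoh = 5.425, v_ac = 4.325),
  h2_poor = list(bounds = c(co = 35, h2 = 10, co2 = 0),
                 mu = 0.72, v_co = -35, v_h2 = -10, v_co2 = 12.5,
                 v_etoh = 0, v_ac = 4.05),
  limited = list(bounds = c(co = 5, h2 = 10, co2 = 0),
                 mu = 41 / 300, v_co = -5, v_h2 = -5, v_co2 = 0,
                 v_etoh = 0, v_ac = 17 / 15)
)

flux_vec <- function(sol)
  c(sol$mu, sol$v_co, sol$v_h2, sol$v_co2, sol$v_etoh, sol$v_ac)

# session-level cache so expensive startup simulations are shared between
# test files
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- force(expr)
  sim_cache[[key]]
}

toy_config <- function(N = 12, t_final = 1000, ...) {
  run_config(settings = list(N = N, t_final = t_final, snapshot_dt = 100),
             ...)
}

# role patterns matching the toy fixture's reaction ids
toy_patterns <- c(co = "^EX_CO$", h2 = "^EX_H2$", co2 = "^EX_CO2$",
                  ethanol = "^EX_ETOH$", acetate = "^EX_AC$",
                  growth = "^BIO$", atp_maintenance = "^ATPM$")
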