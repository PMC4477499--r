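#' Gas uptake kinetics parameter set
#'
#' Nominal dissolved-gas uptake parameters: maximum uptake rates
#' (mmol/gDW/h), Monod saturation constants (mmol/L), a single combined
#' ethanol+acetate product-inhibition constant `K_I` (g/L), and optional
#' CO-inhibition constants `K_I_C` (CO self-inhibition of CO uptake) and
#' `K_I_H` (CO inhibition of H2 uptake), both in g/L of dissolved CO.
#' The defaults `K_I_C = K_I_H = 1e6` g/L correspond to no CO inhibition.
#'
#' @param v_max named vector of maximum uptake rates for `co`, `h2`, `co2`.
#' @param K_m named vector of saturation constants.
#' @param K_I product inhibition constant (g/L).
#' @param K_I_C,K_I_H CO inhibition constants (g/L).
#' @param co_inhibition logical: use the CO-inhibited uptake forms.
#' @return A list of class `syncol_kinetics`.
#' @export
uptake_kinetics <- function(v_max = c(co = 35, h2 = 70, co2 = 35),
                            K_m = c(co = 0.02, h2 = 0.02, co2 = 0.02),
                            K_I = 10,
                            K_I_C = 1e6, K_I_H = 1e6,
                            co_inhibition = FALSE) {
  if (any(c(v_max, K_m, K_I, K_I_C, K_I_H) <= 0))
    abort("all kinetic constants must be positive",
          class = "syncol_config_error")
  structure(list(v_max = v_max, K_m = K_m, K_I = K_I,
                 K_I_C = K_I_C, K_I_H = K_I_H,
                 co_inhibition = co_inhibition),
            class = "syncol_kinetics")
}

#' Gas-phase physical parameters
#'
#' Henry's-law constants (mol/L/atm), gas-liquid mass-transfer
#' coefficients (1/h), temperature, top-of-column pressure, liquid density,
#' and the gas-holdup correlation constants.
#'
#' @param henry named vector `co`, `h2`, `co2` (mol/L/atm).
#' @param k_m named mass-transfer coefficients (1/h).
#' @param temperature K.
#' @param P_top pressure at the top of the column (Pa).
#' @param rho_L liquid density (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @param eps_G_max maximum achievable gas volume fraction.
#' @param K_G holdup saturation constant (m/h).
#' @return A list of class `syncol_gas_params`.
#' @export
gas_physical_params <- function(henry = c(co = 8e-4, h2 = 6.6e-4, co2 = 2.5e-2),
                                k_m = c(co = 80, h2 = 200, co2 = 80),
                                temperature = 310.15,
                                P_top = 1.013e5,
                                rho_L = 1000, g = 9.81,
                                eps_G_max = 0.53, K_G = 540) {
  structure(list(henry = henry, k_m = k_m, temperature = temperature,
                 P_top = P_top, rho_L = rho_L, g = g,
                 eps_G_max = eps_G_max, K_G = K_G),
            class = "syncol_gas_params")
}

#' Monod uptake-rate bound with product inhibition
#'
#' The maximum possible uptake rate of a dissolved gaseous substrate:
#' `v_max * S / (K_m + S) * 1 / (1 + (E + A) / K_I)`.  The result bounds
#' the flux-balance exchange reaction; the realized uptake is whatever the
#' intracellular LP selects within that bound.
#'
#' A regularization factor `S / (S + delta)` with `delta = 1e-6` mmol/L
#' (orders of magnitude below any meaningful dissolved concentration)
#' makes the bound continuously differentiable at zero concentration.
#' Without it the Monod kink at `S = 0` (one-sided slope `v_max / K_m`)
#' turns substrate-exhausted nodes into sliding surfaces that stall the
#' stiff integrator.
#'
#' @param S dissolved substrate concentration (mmol/L), vectorized.
#' @param E,A ethanol and acetate concentrations (g/L).
#' @param kinetics an [uptake_kinetics()] object.
#' @param substrate one of `"co"`, `"h2"`, `"co2"`.
#' @return Uptake bound (mmol/gDW/h), same length as `S`.
#' @export
uptake_bound <- function(S, E = 0, A = 0, kinetics = uptake_kinetics(),
                         substrate = "co") {
  if (any(S < 0) || any(E < 0) || any(A < 0))
    abort("concentrations must be nonnegative", class = "syncol_domain_error")
  v_max <- kinetics$v_max[[substrate]]
  K_m <- kinetics$K_m[[substrate]]
  inhib <- 1 / (1 + (E + A) / kinetics$K_I)
  v_max * S / (K_m + S) * inhib * S / (S + .uptake_delta)
}

# C1 regularization scale for the uptake bounds (mmol/L)
.uptake_delta <- 1e-6

#' CO-inhibited uptake-rate bounds for CO and H2
#'
#' Variant uptake expressions in which high dissolved CO inhibits both its
#' own uptake (substrate-inhibition term `C^2 / K_I_C` in the CO
#' denominator) and H2 uptake (factor `1 / (1 + C / K_I_H)`).  The
#' inhibition constants are quoted in g/L of dissolved CO, so the dissolved
#' CO concentration (mmol/L) is converted with the CO molar mass
#' 28.01 g/mol inside these terms only.  With `K_I_C = K_I_H = 1e6` g/L
#' the expressions reduce to the plain product-inhibited Monod forms.
#'
#' @param C,H dissolved CO and H2 (mmol/L), vectorized.
#' @param E,A ethanol and acetate (g/L).
#' @param kinetics an [uptake_kinetics()] object.
#' @return A list with elements `co` and `h2` (mmol/gDW/h).
#' @export
uptake_bound_co_inhibited <- function(C, H, E = 0, A = 0,
                                      kinetics = uptake_kinetics()) {
  if (any(C < 0) || any(H < 0) || any(E < 0) || any(A < 0))
    abort("concentrations must be nonnegative", class = "syncol_domain_error")
  C_gL <- C * .const$mw_co / 1000  # mmol/L CO -> g/L
  prod_inhib <- 1 / (1 + (E + A) / kinetics$K_I)
  co <- kinetics$v_max[["co"]] * C /
    (kinetics$K_m[["co"]] + C + C * C_gL / kinetics$K_I_C) * prod_inhib *
    C / (C + .uptake_delta)
  h2 <- kinetics$v_max[["h2"]] * H / (kinetics$K_m[["h2"]] + H) *
    prod_inhib / (1 + C_gL / kinetics$K_I_H) * H / (H + .uptake_delta)
  list(co = co, h2 = h2)
}

#' Hydrostatic pressure profile
#'
#' `P(z) = P_top + rho_L * g * (L - z)`: the pressure at height `z` from
#' the liquid head above it, with atmospheric pressure at the top.
#'
#' @param z axial position(s), m, measured from the column bottom.
#' @param geometry list with column length `L` (m).
#' @param params a [gas_physical_params()] object.
#' @return Pressure in Pa.
#' @export
hydrostatic_pressure <- function(z, geometry, params = gas_physical_params()) {
  if (any(z < 0) || any(z > geometry$L))
    abort("z must lie within [0, L]", class = "syncol_domain_error")
  params$P_top + params$rho_L * params$g * (geometry$L - z)
}

#' Gas holdup correlation
#'
#' Saturating fit of gas volume fraction versus superficial gas velocity:
#' `eps_G = eps_G_max * u_G / (K_G + u_G)`.
#'
#' @param u_G superficial gas velocity (m/h), vectorized.
#' @param params a [gas_physical_params()] object.
#' @return Gas volume fraction (dimensionless).
#' @export
gas_holdup <- function(u_G, params = gas_physical_params()) {
  if (any(u_G < 0))
    abort("u_G must be nonnegative", class = "syncol_domain_error")
  params$eps_G_max * u_G / (params$K_G + u_G)
}

#' Henry's-law saturation concentration
#'
#' Converts a gas-phase molar concentration into the dissolved
#' concentration in equilibrium with it.  By default the partial pressure
#' is taken from the gas-phase concentration via the ideal gas law
#' (`p_i = G_i R T`), which reproduces the nominal "calculated" dissolved
#' concentrations exactly.  Setting `P_Pa` (with mole fraction `y`)
#' instead computes `p_i = y_i P(z)`, an alternative convention in which
#' the local hydrostatic pressure enters the equilibrium directly.
#'
#' @param G gas-phase concentration (mmol/L), vectorized.
#' @param henry Henry constant (mol/L/atm).
#' @param temperature K.
#' @param P_Pa optional local total pressure (Pa) for the mole-fraction
#'   convention.
#' @param y mole fraction of the species (only with `P_Pa`).
#' @return Saturated dissolved concentration (mmol/L).
#' @export
saturation_concentration <- function(G, henry, temperature = 310.15,
                                     P_Pa = NULL, y = NULL) {
  if (any(G < 0))
    abort("gas concentration must be nonnegative",
          class = "syncol_domain_error")
  if (is.null(P_Pa)) {
    # G in mmol/L = mol/m^3, so p [Pa] = G * R * T
    p_atm <- G * .const$R_J * temperature / .const$atm_Pa
  } else {
    p_atm <- y * P_Pa / .const$atm_Pa
  }
  henry * p_atm * 1000  # mol/L -> mmol/L
}

#' Feed gas concentrations from mole fractions
#'
#' Ideal-gas molar concentrations of the feed at the bottom-of-column
#' pressure: total concentration `P(0) / (R T)`, split by mole fraction.
#'
#' @param x named mole fractions `co`, `h2`, `co2` (must sum to 1).
#' @param geometry list with column length `L`.
#' @param params a [gas_physical_params()] object.
#' @return Named vector of feed gas concentrations (mmol/L).
#' @export
feed_gas_concentrations <- function(x = c(co = 0.6, h2 = 0.4, co2 = 0),
                                    geometry = list(L = 25),
                                    params = gas_physical_params()) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-12)
    abort("feed mole fractions must be nonnegative and sum to 1",
          class = "syncol_config_error")
  P0 <- hydrostatic_pressure(0, geometry, params)
  total <- P0 / (.const$R_J * params$temperature)  # mol/m^3 = mmol/L
  x * total
}
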