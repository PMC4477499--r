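---
title: "The syncol column model: equations, assumptions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The syncol column model: equations, assumptions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`syncol` simulates syngas fermentation in a bubble column by embedding a
constraint-based model of acetogen metabolism into multiphase
convection–dispersion balances.  This vignette is the package's own
account of the model: what is solved, which knobs matter, which numerical
choices were made and why, and what the simulations do and do not say
about real reactors.

## Model structure

### Intracellular metabolism: lexicographic FBA

At every axial node the cell is represented by a stoichiometric network
at pseudo-steady state, `S v = 0` with per-reaction flux bounds
(mmol/gDW/h).  The growth rate and exchange fluxes are obtained by
solving an ordered sequence of linear programs:

1. maximize growth rate μ,
2. maximize CO uptake,
3. maximize H₂ uptake,
4. minimize CO₂ synthesis,
5. minimize acetate synthesis,
6. minimize ethanol synthesis,

fixing each optimum as a two-sided constraint (relative tolerance 1e-9,
absolute floor 1e-12) before the next solve.  Optimal exchange fluxes of
an FBA problem are generally non-unique; the lexicographic ordering makes
the reported fluxes unique functions of the bounds, without which the
outer ODE system would not have a well-defined right-hand side.  Because
every objective is a single flux coordinate, "fixing" is implemented as
bound tightening, so all six stages share one factorized basis and
warm-start each other.

Uptake bounds enter with the convention that kinetic rates are positive
magnitudes applied as lower bounds `-v_i` on the exchange reactions;
exchange flux is negative in consumption and positive in secretion, and
the transport equations consume the signed fluxes directly.  The CO₂
exchange is left free in both directions up to its kinetic uptake bound,
so dissolved CO₂ can be reassimilated through the carbon-fixation
pathway.

**Maintenance and starvation.**  A mandatory ATP-maintenance flux makes
the LP infeasible when gas uptake is too small; such cells generate no
growth.  Reporting *zero* fluxes in that case — the obvious contract —
creates a sliding-mode discontinuity at the growth/no-growth boundary
(no uptake lets dissolved gas recover, which re-enables full uptake,
which exhausts the gas again), and a stiff integrator grinds to machine-
epsilon steps on such a surface.  `syncol` instead treats infeasibility
as *starvation*: the maintenance lower bound is relaxed, the achievable
maintenance flux (capped at the demand) is maximized as a prepended
objective, and the usual sequence follows.  Growth is then zero, cells
keep scavenging what gas they can, and the flux response is continuous
across the boundary.  With zero uptake bounds the starving solution is
identically zero, so the limiting behaviour is unchanged.

### Uptake kinetics

Bounds follow product-inhibited Monod kinetics,

`v_i = v_max,i · S_i/(K_m,i + S_i) · 1/(1 + (E + A)/K_I)`,

with defaults `v_max` = 35 (CO), 70 (H₂), 35 (CO₂) mmol/gDW/h, all
`K_m` = 0.02 mmol/L, and a single combined ethanol+acetate inhibition
constant `K_I` = 10 g/L (both products are assumed equally inhibitory so
one constant suffices).  An optional CO-inhibited variant adds substrate
inhibition of CO uptake (`C²/K_I_C` in the denominator) and CO
cross-inhibition of H₂ uptake (`1/(1 + C/K_I_H)`); the inhibition
constants are quoted in g/L of dissolved CO, so the mmol/L concentration
is converted with the CO molar mass (28.01 g/mol) inside those terms
only.  At `K_I_C = K_I_H = 1e6` g/L the variant coincides with the plain
form to well below 1e-4 relative, which is the no-inhibition default.

All bounds carry a regularization factor `S/(S + δ)` with δ = 1e-6
mmol/L.  This is numerically essential: nodes whose substrate is
exhausted sit exactly on the Monod kink at `S = 0`, whose one-sided slope
`v_max/K_m` = 1750 L/mmol/h turns the exhaustion surface into another
sliding mode.  The factor makes the bound C¹ at zero while changing any
physically meaningful value by less than 1e-6 relative (δ is ~1 nM).

### Gas–liquid coupling and pressure

Saturation concentrations follow Henry's law, `C* = H_i p_i` with `H_i`
in mol/L/atm (CO 8e-4, H₂ 6.6e-4, CO₂ 2.5e-2).  The partial pressure is
taken from the gas-phase molar concentration via the ideal gas law,
`p_i = G_i R T`: this convention reproduces the nominal "calculated"
operating-point values exactly (feed 80.64 / 53.76 mmol/L, saturated
1.642 / 0.903 mmol/L) because the hydrostatic pressure enters once,
through the feed concentration evaluated at bottom-of-column pressure
`P(0) = P_top + ρ g L`.  An alternative convention, `p_i = y_i P(z)`
with the local head, is also implemented
(`gas$henry_convention = "local_pressure"`) since gases plausibly
dissolve more readily at depth; it is not the default because it does
not reproduce the nominal dissolved values.  The gas constant is
R = 8.314 J/mol/K with 1 atm = 101325 Pa; the nominal feed values
reproduce to their printed precision only with this engineering value
(8.31446 gives 80.63 rather than 80.64 mmol/L).

Gas holdup is evaluated once from the feed superficial velocity with the
saturating correlation `ε_G = ε_G,max u_G/(K_G + u_G)`
(`ε_G,max` = 0.53, `K_G` = 540 m/h; 0.0646 at the nominal
u_G = 75 m/h) and held constant in space and time, as are both
superficial velocities — consistent with the constant-coefficient form
of the gas-phase balances.

### Transport

Nine fields per node: biomass X (g/L), dissolved CO/H₂/CO₂ (mmol/L),
ethanol and acetate (g/L), and gas-phase CO/H₂/CO₂ (mmol/L).  Liquid
fields follow convection–dispersion with biological source terms
(`μX`, `v_i X`, `M_E v_E X`, `M_A v_A X`) and gas–liquid transfer
`(k_m,i/ε_L)(C* - C_L)`; gas fields are pure convection with the
opposite transfer sink `-(k_m,i/ε_G)(C* - C_L)`, so transfer conserves
moles pointwise after volume-fraction weighting.  Both phases flow
upward (co-current); the liquid feed carries no cells, products or
dissolved gas.  Molecular weights are `M_E` = 0.04607 g/mmol and
`M_A` = 0.06005 g/mmol (acetic acid; the acetate weight is a package
choice as only ethanol's is conventionally fixed by the balances).

Boundary conditions: liquid fields satisfy the Danckwerts flux balance
`u_L f(0) - ε_L D_A f'(0) = u_L f_feed` (all liquid feed values zero) at
the inlet and zero slope at the exit; gas fields are pinned to the feed
concentration at the inlet (Dirichlet) and need no exit condition.

## Discretization and integration

The column is discretized on a uniform grid of `N` nodes (default 100;
node 1 at the inlet).  Convection uses the four-point third-order
upwind-biased stencil

`(2 f[j+1] + 3 f[j] - 6 f[j-1] + f[j-2]) / (6 Δz)`,

which is exact through cubics; nodes adjacent to the boundaries fall
back to first-order upwind, a standard choice that preserves stability
without ghost-node proliferation (a pure first-order scheme is available
via `settings$scheme`).  Dispersion uses second-order central
differences.  Boundary conditions close the stencils through ghost
values: the Danckwerts condition with a central inlet gradient gives
`ghost = f[2] - 2Δz u_L f[1]/(ε_L D_A)`, which degenerates to Dirichlet
inflow as `D_A → 0`; the zero-slope exit gives `ghost = f[N-1]`.

**The no-cell initial state is not exactly stationary.**  The initial
condition (uniform biomass 0.1 g/L, liquid saturated with the feed
gases, gas phase equal to the feed) is often described as a steady state
without cells, but the printed Danckwerts conditions feed *gas-free*
liquid, so the continuous problem necessarily develops a thin dissolved-
gas boundary layer at the inlet (analytically ~5 cm wide, ~5 % deep at
the nominal parameters, replenished by transfer from the gas).  With
`X₀ = 0` the package therefore holds biomass, products and — to the
make-up flux — the gas phase stationary, while dissolved gases relax
only inside the first metre.  No discretization can remove this; it is a
property of the stated boundary conditions.

Time integration uses `deSolve::lsoda` with an analytic banded Jacobian
(interleaved state ordering gives bandwidths 17 above / 26 below): the
constant linear part — transfer, convection, dispersion, including the
ghost closures — is assembled once, and the biological block is added
per evaluation from one-sided differences of the per-node LP solves
(the flux solution is piecewise linear in the local concentrations, so
these differences are exact almost everywhere).  Default tolerances are
rtol 1e-6 / atol 1e-8, chosen so that halving them moves steady-state
exit metrics by well under 0.1 %.  The horizon is integrated in chunks
with the max-norm of the right-hand side checked at chunk ends; the run
stops early and is flagged steady when the norm falls below
`settings$steady_tol` (default 1e-3 in field units per hour, which the
nominal toy column reaches by ~350 h of its 1000 h horizon).  The
right-hand side and Jacobian are compiled (C++), with one
lexicographic solve per node per evaluation and per-node warm-started
bases persisting across evaluations; a pure-R reference implementation
of the same right-hand side is kept and cross-checked in the tests.

## Drivers

`steady_state_metrics()` reads the exit (top) node: titers, dissolved
and gas concentrations, ethanol/acetate ratio, and conversions
`1 - G(L)/G_feed`.  Conversion is concentration-based; with constant
`u_G` it coincides with the molar-flow definition.  The ratio is a mass
basis (g/L over g/L), since titers are reported in g/L; it is `Inf`
(serialized as `null` plus a flag) when acetate is below 1e-6 g/L.

`apply_gas_recycle()` mixes a fraction α of the exit gas into the fresh
feed *at fixed total inlet molar concentration*: recycle displaces fresh
feed rather than increasing throughput, which keeps `u_G` and `ε_G` at
their configured values and isolates the composition effect of recycle.
The recycle simulation iterates startup → inlet update until the inlet
composition changes by < 1e-4 relative (at most 50 passes).

`run_parameter_sweep()` runs one full startup per parameter value,
records failed rows without aborting the sweep, and
`interpolate_sweep()` provides the linear interpolation used for trend
curves between simulated cases.

## The toy Wood–Ljungdahl network

Tests and examples run on `toy_wlp_network()`, a nine-metabolite lump of
acetogen physiology: CO and H₂ oxidation feed a reducing-equivalent pool
(2 per gas molecule), carbon fixation consumes 2 CO₂ + 8 reducing
equivalents per acetyl-CoA, and acetyl-CoA splits between acetate
(yielding 1 ATP by substrate-level phosphorylation — the *sole* ATP
source), ethanol (4 further reducing equivalents), and biomass
(10 acetyl-CoA + 5 ATP, capped at `mu_max` = 0.775 h⁻¹ to represent
finite biosynthetic machinery).  Maintenance demands 0.45 mmol ATP/gDW/h.

This energy coupling was chosen deliberately:

* acetate is obligatory whenever the cell grows (growth ATP comes from
  acetate kinase), so product fields in the column are smooth and
  grid-convergent rather than confined to a boundary layer;
* at H₂-rich, carbon-limited bounds the surplus electrons discharge into
  ethanol (at bounds CO 35 / H₂ 70: μ = 0.775, ethanol 5.425 > acetate
  4.325 mmol/gDW/h, H₂ uptake self-limited to 45.85), while H₂-poor
  bounds yield acetate only — the qualitative CO/H₂ product split of
  CO-fermenting acetogens;
* after the three maximization stages the solution is fully determined,
  so permuting the three minimization objectives does not change the
  exchange fluxes, mirroring the behaviour of the genome-scale
  reconstruction;
* bounds too small to cover maintenance are infeasible (zero growth).

What the toy network does *not* emulate: realistic yields (its steady
columns accumulate acetate to hundreds of g/L because biomass and ATP
are cheap), byproduct spectra beyond ethanol/acetate/CO₂, or any genome
scale redundancy.  Passing tests on the toy network therefore validate
the *machinery* — LP ordering, kinetics, transport, steady-state logic —
not quantitative predictions for *C. ljungdahlii*; those require the
iHN637 reconstruction, which users must obtain themselves (BiGG Models)
and which drives hours-scale simulations.

## Test and verification scales

The test suite exercises startup simulations at 8–40 nodes with the
steady-state early exit, plus one 100- and one 200-node run for the
grid-convergence check (exit metrics agree to ≪1 % between them, with
each run finishing in well under a minute); LP solutions are frozen
against values computed independently with an external constraint-based
modelling toolchain and cross-checked against a second LP
implementation; the compiled right-hand side is compared with the
reference R implementation, and the analytic Jacobian with finite
differences.

## Known limitations

* Hydrodynamics are idealized: constant holdup and velocities, no
  bubble-size distribution, no radial structure, no gas-phase dispersion.
* pH is constant; product inhibition is lumped into a single constant
  acting identically on all uptakes.
* The CO-inhibition constants of the variant kinetics have no nominal
  values (no-inhibition defaults of 1e6 g/L); "moderate" and "strong"
  inhibition are user choices.
* The growth/no-growth and substrate-exhaustion boundaries are
  regularized (starvation mode, C¹ uptake bounds); trajectories within ~1 nM of
  exhaustion or exactly at the maintenance threshold are smoothed
  representations of non-smooth limits.
* Steady states are found by long-horizon integration with an RHS-norm
  check, not by a Newton solve; columns that oscillate would be reported
  honestly as `steady = FALSE`.
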