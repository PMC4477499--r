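# Spatial discretization operators and the assembled right-hand side.

test_that("upwind convection is exact for polynomials through cubics", {
  N <- 30; L <- 25
  g <- axial_grid(N, L)
  z <- g$z; dz <- g$dz
  interior <- 3:(N - 1)
  # constant
  d <- convective_derivative(rep(3, N), dz, ghost0 = 3)
  expect_equal(d, rep(0, N), tolerance = 1e-14)
  # linear: exact at all nodes given the exact ghost
  f <- 2 + 0.5 * z
  d <- convective_derivative(f, dz, ghost0 = 2 + 0.5 * (z[1] - dz))
  expect_equal(d, rep(0.5, N), tolerance = 1e-12)
  # quadratic and cubic: exact at interior nodes (third-order stencil)
  f <- z^2
  d <- convective_derivative(f, dz)
  expect_equal(d[interior], 2 * z[interior], tolerance = 1e-10)
  f <- z^3 - 4 * z^2 + z
  d <- convective_derivative(f, dz)
  expect_equal(d[interior], 3 * z[interior]^2 - 8 * z[interior] + 1,
               tolerance = 1e-9)
  # first-order variant is only linear-exact
  d1 <- convective_derivative(f, dz, scheme = "first-order-upwind")
  expect_gt(max(abs(d1[interior] -
                      (3 * z[interior]^2 - 8 * z[interior] + 1))), 1)
})

test_that("central dispersion is exact for quadratics and 2nd-order accurate", {
  N <- 40; L <- 25
  g <- axial_grid(N, L)
  z <- g$z; dz <- g$dz
  mid <- 2:(N - 1)
  expect_equal(dispersive_derivative(z^2, dz)[mid], rep(2, N - 2),
               tolerance = 1e-9)
  expect_equal(dispersive_derivative(1 + 3 * z, dz)[mid], rep(0, N - 2),
               tolerance = 1e-11)
  # halving dz reduces the error on a smooth field by about 4x
  err <- sapply(c(40, 80), function(n) {
    gg <- axial_grid(n, L)
    f <- sin(gg$z / 3)
    d <- dispersive_derivative(f, gg$dz)
    j <- 2:(n - 1)
    max(abs(d[j] + sin(gg$z[j] / 3) / 9))
  })
  expect_gt(err[1] / err[2], 3.4)
  expect_lt(err[1] / err[2], 4.6)
})

test_that("boundary closures satisfy the stated conditions", {
  u_L <- 0.25; eps_L <- 0.9354; D_A <- 0.25; dz <- 0.25
  f <- c(1.3, 1.1, 0.9, 0.8, 0.7)
  bc <- apply_boundary_conditions(f, "liquid", 0, u_L, eps_L, D_A, dz)
  # Danckwerts flux balance with the central inlet gradient
  resid <- u_L * f[1] - eps_L * D_A * (f[2] - bc$ghost0) / (2 * dz)
  expect_equal(resid, 0, tolerance = 1e-12)
  expect_equal(bc$ghostN1, f[4])
  # uniform zero field with zero feed has zero closure residual
  bc0 <- apply_boundary_conditions(rep(0, 5), "liquid", 0, u_L, eps_L, D_A, dz)
  expect_identical(bc0$ghost0, 0)
  # vanishing dispersion reduces Danckwerts to a Dirichlet inflow
  bcd <- apply_boundary_conditions(f, "liquid", 0.5, u_L, eps_L, 1e-14, dz)
  expect_identical(bcd$ghost0, 0.5)
  bg <- apply_boundary_conditions(f, "gas", 42, u_L, eps_L, D_A, dz)
  expect_identical(bg$ghost0, 42)
  expect_error(apply_boundary_conditions(f, "plasma"),
               class = "syncol_config_error")
})

net <- toy_wlp_network()

test_that("the no-cell saturated column is stationary away from the inlet", {
  cfg <- run_config(settings = list(N = 40), initial = list(X0 = 0))
  st <- initial_column_state(cfg, net)
  d <- assemble_rhs(0, st, net, cfg)
  dm <- as.matrix(d[, paste0("d", syncol:::.fields)])
  # biomass, products and the entire gas phase are exactly stationary
  expect_lt(max(abs(dm[, c(1, 5, 6, 7, 8, 9)])), 1e-10)
  # dissolved gases are stationary except in the inlet Danckwerts layer,
  # where gas-free feed liquid enters (the printed boundary conditions
  # force a boundary layer there; see the methods vignette)
  expect_lt(max(abs(dm[4:40, 2:4])), 1e-9)
  expect_gt(max(abs(dm[1, 2:3])), 0.1)
})

test_that("gas-liquid transfer conserves moles between the phases", {
  # isolate the transfer terms by differencing two engines that differ
  # only in the mass-transfer coefficients (biology is unaffected)
  N <- 10
  cfg1 <- run_config(settings = list(N = N))
  cfg2 <- run_config(settings = list(N = N),
                     gas = list(k_m = c(co = 1e-9, h2 = 1e-9, co2 = 1e-9)))
  der <- syncol:::config_derived(cfg1)
  eng1 <- syncol:::build_column_engine(net, cfg1)
  eng2 <- syncol:::build_column_engine(net, cfg2)
  set.seed(7)
  st <- cbind(X = runif(N, 0, 2), C_L = runif(N, 0, 1),
              H_L = runif(N, 0, 0.5), D_L = runif(N, 0, 0.2),
              E_L = runif(N, 0, 2), A_L = runif(N, 0, 2),
              C_G = runif(N, 40, 80), H_G = runif(N, 20, 50),
              D_G = runif(N, 0, 5))
  y <- as.vector(t(st))
  d1 <- t(matrix(syncol:::engine_rhs(0, y, eng1)[[1]], nrow = 9))
  d2 <- t(matrix(syncol:::engine_rhs(0, y, eng2)[[1]], nrow = 9))
  tr <- d1 - d2
  # nodes 2..N (gas inlet node is pinned to the feed)
  for (k in 1:3) {
    bal <- der$eps_L * tr[2:N, 1 + k] + der$eps_G * tr[2:N, 6 + k]
    expect_lt(max(abs(bal)), 1e-8)
  }
  # undersaturated liquid gains from the gas phase
  cstar <- eng1$hf_gc[["co"]] * st[, "C_G"]
  expect_true(all((tr[2:N, 2] > 0) == (cstar > st[, "C_L"])[2:N]))
})

test_that("product source terms follow the molecular-weight bookkeeping", {
  cfg <- run_config(settings = list(N = 10))
  eng <- syncol:::build_column_engine(net, cfg)
  N <- 10
  st <- cbind(X = seq(0.5, 5, length.out = N), C_L = 1.642, H_L = 0.903,
              D_L = 0, E_L = 0, A_L = 0, C_G = 0, H_G = 0, D_G = 0)
  r <- syncol:::engine_rhs(0, as.vector(t(st)), eng, want_flux = TRUE)
  dm <- t(matrix(r$dy, nrow = 9))
  expect_equal(dm[2:N, 5], 0.04607 * r$flux[2:N, "v_etoh"] * st[2:N, "X"],
               tolerance = 1e-10)
  expect_equal(dm[2:N, 6], 0.06005 * r$flux[2:N, "v_ac"] * st[2:N, "X"],
               tolerance = 1e-10)
})

test_that("compiled and reference right-hand sides agree", {
  cfg <- run_config(settings = list(N = 15))
  eng <- syncol:::build_column_engine(net, cfg)
  set.seed(11)
  for (i in 1:3) {
    st <- initial_column_state(cfg, net)
    y <- as.vector(t(st)) * runif(15 * 9, 0.5, 1.5)
    rC <- syncol:::engine_rhs(0, y, eng, want_flux = TRUE)
    rR <- syncol:::engine_rhs_r(0, y, eng, want_flux = TRUE)
    expect_equal(rC$dy, rR$dy, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(unname(rC$flux), unname(rR$flux), tolerance = 1e-9)
  }
})

test_that("the banded Jacobian matches finite differences of the RHS", {
  cfg <- run_config(settings = list(N = 8))
  eng <- syncol:::build_column_engine(net, cfg)
  y0 <- as.vector(t(initial_column_state(cfg, net)))
  y0[seq(1, length(y0), 9)] <- 2  # active biology
  f0 <- syncol:::engine_rhs(0, y0, eng)[[1]]
  pack <- syncol:::engine_jac(0, y0, eng)
  set.seed(3)
  cols <- sample(length(y0), 15)
  for (j in cols) {
    h <- 1e-7 * max(abs(y0[j]), 1e-2)
    yp <- y0; yp[j] <- yp[j] + h
    dnum <- (syncol:::engine_rhs(0, yp, eng)[[1]] - f0) / h
    for (i in seq_along(y0)) {
      r <- 17 + 1 + i - j
      ja <- if (r >= 1 && r <= 44) pack[r, j] else 0
      if (abs(dnum[i]) > 1e-3)
        expect_equal(ja, dnum[i], tolerance = 2e-2)
    }
  }
})

test_that("grids narrower than the stencil are rejected", {
  expect_error(axial_grid(4, 25), class = "syncol_grid_error")
  expect_error(convective_derivative(c(1, 2, 3), 0.1),
               class = "syncol_grid_error")
})
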