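# Uptake kinetics, holdup, pressure, Henry's-law and feed-gas arithmetic.

kin <- uptake_kinetics()
gp <- gas_physical_params()
geo <- list(L = 25)

test_that("gas holdup reproduces the nominal operating point", {
  expect_lt(abs(gas_holdup(75, gp) - 0.0646), 5e-5)
  expect_identical(gas_holdup(0, gp), 0)
  expect_equal(gas_holdup(1e9, gp), 0.53, tolerance = 1e-5)
  u <- seq(0, 2000, by = 50)
  eg <- gas_holdup(u, gp)
  expect_true(all(diff(eg) > 0))
  expect_true(all(eg < 0.53))
})

test_that("Monod uptake bound matches hand-evaluated values", {
  expect_identical(uptake_bound(0, 5, 3, kin, "co"), 0)
  expect_equal(uptake_bound(1.642, 0, 0, kin, "co"),
               35 * 1.642 / (0.02 + 1.642), tolerance = 1e-5)
  expect_equal(uptake_bound(1.642, 0, 0, kin, "co"), 34.579,
               tolerance = 1e-4)
  # E + A = K_I halves the rate
  expect_equal(uptake_bound(1.642, 4, 6, kin, "co"),
               uptake_bound(1.642, 0, 0, kin, "co") / 2, tolerance = 1e-12)
  expect_error(uptake_bound(-1, 0, 0, kin, "co"),
               class = "syncol_domain_error")
})

test_that("uptake bound is monotone in substrate and products", {
  S <- seq(0, 50, by = 0.5)
  b <- uptake_bound(S, 0, 0, kin, "co")
  expect_true(all(diff(b) > 0))
  expect_lt(max(b), 35)
  expect_equal(uptake_bound(1e7, 0, 0, kin, "co"), 35, tolerance = 1e-4)
  E <- seq(0, 50, by = 1)
  bE <- uptake_bound(1.642, E, 0, kin, "co")
  expect_true(all(diff(bE) < 0))
  bA <- uptake_bound(1.642, 0, E, kin, "co")
  expect_identical(bE, bA)  # equal inhibition by either product
})

test_that("CO-inhibited forms reduce to the plain forms without inhibition", {
  C <- c(0.01, 0.1, 0.5, 1.642, 5, 20)
  H <- c(0.005, 0.05, 0.3, 0.903, 3, 15)
  b <- uptake_bound_co_inhibited(C, H, 1, 2, kin)
  expect_equal(b$co, uptake_bound(C, 1, 2, kin, "co"), tolerance = 1e-4)
  expect_equal(b$h2, uptake_bound(H, 1, 2, kin, "h2"), tolerance = 1e-4)
})

test_that("CO self-inhibition rolls the CO uptake over at high CO", {
  kin2 <- uptake_kinetics(K_I_C = 0.5, K_I_H = 0.5)
  C <- c(10, 100, 1000, 1e5)
  b <- uptake_bound_co_inhibited(C, 0.9, 0, 0, kin2)
  expect_true(all(diff(b$co) < 0))
  expect_lt(b$co[4], 0.2)
  # H2 uptake halves when dissolved CO (in g/L) equals K_I_H
  C_half <- 0.5 / (28.01 / 1000)  # mmol/L giving 0.5 g/L
  b2 <- uptake_bound_co_inhibited(C_half, 0.903, 0, 0, kin2)
  b0 <- uptake_bound(0.903, 0, 0, kin2, "h2")
  expect_equal(b2$h2, b0 / 2, tolerance = 1e-3)
})

test_that("hydrostatic pressure follows the liquid head", {
  expect_equal(hydrostatic_pressure(25, geo, gp), 1.013e5)
  expect_equal(hydrostatic_pressure(0, geo, gp), 3.4655e5)
  gp0 <- gas_physical_params(rho_L = 1e-30)
  expect_equal(hydrostatic_pressure(c(0, 12.5, 25), geo, gp0),
               rep(1.013e5, 3), tolerance = 1e-6)
  expect_error(hydrostatic_pressure(-1, geo, gp),
               class = "syncol_domain_error")
  expect_error(hydrostatic_pressure(26, geo, gp),
               class = "syncol_domain_error")
})

test_that("Henry saturation reproduces the nominal dissolved values", {
  expect_equal(saturation_concentration(80.64, 8e-4), 1.642,
               tolerance = 5e-4)
  expect_equal(saturation_concentration(53.76, 6.6e-4), 0.903,
               tolerance = 5e-4)
  expect_identical(saturation_concentration(0, 8e-4), 0)
  # linear in the gas concentration
  g <- c(1, 2.5, 10, 80)
  s <- saturation_concentration(g, 8e-4)
  expect_equal(s, g * s[1], tolerance = 1e-12)
  expect_error(saturation_concentration(-1, 8e-4),
               class = "syncol_domain_error")
})

test_that("feed gas concentrations follow the ideal gas law at P(0)", {
  feed <- feed_gas_concentrations(c(co = 0.6, h2 = 0.4, co2 = 0), geo, gp)
  expect_equal(unname(feed[["co"]]), 80.64, tolerance = 1e-4)
  expect_equal(unname(feed[["h2"]]), 53.76, tolerance = 1e-4)
  expect_identical(unname(feed[["co2"]]), 0)
  pure <- feed_gas_concentrations(c(co = 1, h2 = 0, co2 = 0), geo, gp)
  expect_equal(unname(pure[["co"]]), sum(feed) / 1, tolerance = 1e-10)
  expect_error(feed_gas_concentrations(c(co = 0.7, h2 = 0.4, co2 = 0), geo, gp),
               class = "syncol_config_error")
})

test_that("the local-pressure Henry convention responds to depth", {
  s_top <- saturation_concentration(80, 8e-4, P_Pa = 1.013e5, y = 0.6)
  s_bot <- saturation_concentration(80, 8e-4, P_Pa = 3.4655e5, y = 0.6)
  expect_gt(s_bot, s_top)
  expect_equal(s_bot / s_top, 3.4655 / 1.013, tolerance = 1e-10)
})
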