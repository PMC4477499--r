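# Startup integration, steady-state metrics, recycle and sweeps.

net <- toy_wlp_network()

test_that("a cell-free column stays at its initial state", {
  cfg <- run_config(settings = list(N = 12, t_final = 50, snapshot_dt = 25),
                    initial = list(X0 = 0))
  res <- cached_sim("nocell12", simulate_startup(cfg, net))
  st0 <- initial_column_state(cfg, net)
  fs <- res$final_state
  # biomass and products: unchanged to integrator accuracy; the gas
  # phase moves only by the tiny make-up flux into the inlet layer
  expect_lt(max(abs(fs[, c("X", "E_L", "A_L")] -
                      st0[, c("X", "E_L", "A_L")])), 1e-6)
  expect_lt(max(abs(fs[, c("C_G", "H_G", "D_G")] -
                      st0[, c("C_G", "H_G", "D_G")])), 1e-3)
  expect_true(res$steady)
  # dissolved gases: unchanged except the inlet Danckwerts boundary layer
  # fed by gas-free liquid (sub-percent of saturation, first metre only)
  expect_lt(max(abs(fs[4:12, c("C_L", "H_L")] - st0[4:12, c("C_L", "H_L")])),
            1e-4)
  expect_lt(max(abs(fs[, "C_L"] - st0[, "C_L"])) / 1.642, 0.06)
})

test_that("nominal startup reaches a growing, acetogenic steady state", {
  cfg <- toy_config(N = 20)
  res <- cached_sim("nominal20", simulate_startup(cfg, net))
  expect_true(res$steady)
  m <- steady_state_metrics(res)
  expect_gt(m$X_gL, 1)
  expect_gt(m$ac_gL, 1)           # growth-coupled acetate
  expect_gt(m$co_conversion, 0.1)
  expect_gt(m$h2_conversion, m$co_conversion)  # faster H2 transfer
  expect_true(m$co_conversion < 1 && m$h2_conversion < 1)
  # steady-state verification: re-evaluated RHS norm below threshold
  eng <- syncol:::build_column_engine(net, cfg)
  rhs <- syncol:::engine_rhs(res$final_time, as.vector(t(res$final_state)),
                             eng)[[1]]
  expect_lt(max(abs(rhs)), cfg$settings$steady_tol)
  # gas profiles decrease monotonically up the column (consumption only)
  expect_true(all(diff(res$final_state[, "C_G"]) < 1e-9))
  expect_true(all(diff(res$final_state[, "H_G"]) < 1e-9))
})

test_that("identical configurations give identical results", {
  cfg <- toy_config(N = 10, t_final = 60)
  r1 <- simulate_startup(cfg, net)
  r2 <- simulate_startup(cfg, net)
  expect_identical(r1$final_state, r2$final_state)
  expect_identical(steady_state_metrics(r1), steady_state_metrics(r2))
})

test_that("halving the integrator tolerances barely moves the metrics", {
  cfg1 <- toy_config(N = 10)
  cfg2 <- run_config(settings = list(N = 10, t_final = 1000,
                                     snapshot_dt = 100,
                                     rtol = 5e-7, atol = 5e-9))
  m1 <- steady_state_metrics(cached_sim("tol10a", simulate_startup(cfg1, net)))
  m2 <- steady_state_metrics(cached_sim("tol10b", simulate_startup(cfg2, net)))
  for (k in c("X_gL", "ac_gL", "co_conversion", "h2_conversion")) {
    expect_lt(abs(m1[[k]] - m2[[k]]) / abs(m1[[k]]), 1e-3)
  }
})

test_that("metrics handle the edge cases of the conversion and ratio", {
  mk_result <- function(exitrow) {
    st <- matrix(rep(exitrow, each = 5), nrow = 5,
                 dimnames = list(NULL, syncol:::.fields))
    structure(list(final_state = st, steady = TRUE,
                   feed = c(co = 80.64, h2 = 53.76, co2 = 0)),
              class = "syncol_result")
  }
  m <- steady_state_metrics(mk_result(
    c(1, 0, 0, 0, 0, 0, 80.64, 53.76, 0)))
  expect_equal(m$co_conversion, 0)
  m <- steady_state_metrics(mk_result(c(1, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(m$co_conversion, 1)
  expect_equal(m$h2_conversion, 1)
  m <- steady_state_metrics(mk_result(c(1, 0, 0, 0, 2.5, 0, 40, 20, 0)))
  expect_identical(m$ethanol_acetate_ratio, Inf)  # acetate below 1e-6 g/L
})

test_that("gas recycle mixes compositions at fixed total concentration", {
  fresh <- c(co = 80.64, h2 = 53.76, co2 = 0)
  expect_equal(apply_gas_recycle(fresh, c(co = 40, h2 = 30, co2 = 5), 0),
               fresh)
  # recycling gas of feed composition changes nothing at any alpha
  for (a in c(0.2, 0.5, 0.9))
    expect_equal(apply_gas_recycle(fresh, fresh * 0.37, a), fresh,
                 tolerance = 1e-12)
  mixed <- apply_gas_recycle(fresh, c(co = 10, h2 = 40, co2 = 10), 0.5)
  expect_equal(sum(mixed), sum(fresh), tolerance = 1e-12)
  expect_lt(mixed[["co"]], fresh[["co"]])
  expect_error(apply_gas_recycle(fresh, fresh, 1),
               class = "syncol_config_error")
})

test_that("a single-value sweep equals a single simulation", {
  cfg <- toy_config(N = 10, t_final = 400)
  sw <- run_parameter_sweep(cfg, "geometry.u_G", 75, net)
  expect_s3_class(sw, "syncol_sweep")
  expect_identical(nrow(sw), 1L)
  ref <- steady_state_metrics(simulate_startup(cfg, net))
  expect_equal(sw$X_gL, ref$X_gL, tolerance = 1e-12)
  expect_true(is.na(sw$error))
})

test_that("failed sweep rows are recorded and the sweep continues", {
  cfg <- toy_config(N = 10, t_final = 400)
  sw <- run_parameter_sweep(cfg, "settings.t_final", c(-5, 400), net)
  expect_identical(nrow(sw), 2L)
  expect_false(is.na(sw$error[1]))
  expect_true(is.na(sw$error[2]))
})

test_that("sweep interpolation is linear between simulated cases", {
  sw <- tibble::tibble(value = c(1, 2, 3), X_gL = c(0, 10, 40),
                       error = NA_character_)
  attr(sw, "param") <- "demo"
  li <- interpolate_sweep(sw, "X_gL", n = 5)
  expect_equal(li$X_gL, c(0, 5, 10, 25, 40))
})

test_that("tidiers and plots expose the result as tables and figures", {
  res <- cached_sim("nominal20", simulate_startup(toy_config(N = 20), net))
  tl <- tidy(res)
  expect_true(all(c("time_h", "z_m", "field", "value") %in% names(tl)))
  expect_identical(nrow(tl), length(res$times) * 20L * 9L)
  g <- glance(res)
  expect_s3_class(g, "syncol_metrics")
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
  sw <- tibble::tibble(value = c(1, 2), X_gL = c(1, 2), etoh_gL = c(0, 1),
                       ac_gL = c(1, 0), co_conversion = c(.1, .2),
                       h2_conversion = c(.3, .4), error = NA_character_)
  class(sw) <- c("syncol_sweep", class(sw))
  p2 <- ggplot2::autoplot(sw)
  expect_s3_class(p2, "ggplot")
})
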