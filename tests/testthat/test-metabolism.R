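# Lexicographic flux-balance behaviour of the toy Wood-Ljungdahl fixture
# and the model loaders.

net <- toy_wlp_network()

test_that("toy network satisfies the container invariants", {
  expect_s3_class(net, "syncol_network")
  expect_equal(dim(net$S), c(length(net$metabolites), length(net$reactions)))
  expect_true(all(net$exchange %in% net$reactions))
  expect_gt(net$lower[[net$exchange[["atp_maintenance"]]]], 0)
  expect_setequal(names(net$exchange),
                  c("co", "h2", "co2", "ethanol", "acetate", "growth",
                    "atp_maintenance"))
})

test_that("lexicographic solutions match independently computed optima", {
  for (cs in lex_oracle) {
    sol <- solve_lexicographic_fba(net, cs$bounds)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$mu, cs$mu, tolerance = 1e-7)
    expect_equal(sol$v_co, cs$v_co, tolerance = 1e-6)
    expect_equal(sol$v_h2, cs$v_h2, tolerance = 1e-6)
    expect_equal(sol$v_co2, cs$v_co2, tolerance = 1e-6)
    expect_equal(sol$v_etoh, cs$v_etoh, tolerance = 1e-6)
    expect_equal(sol$v_ac, cs$v_ac, tolerance = 1e-6)
    # steady-state stoichiometric consistency
    expect_lt(max(abs(as.matrix(net$S) %*% sol$fluxes)), 1e-8)
    # bound respect: [-uptake bound, upper] for exchanges, model bounds else
    lo <- net$lower
    lo[net$exchange[c("co", "h2", "co2")]] <- -cs$bounds
    expect_true(all(sol$fluxes >= lo - 1e-8))
    expect_true(all(sol$fluxes <= net$upper + 1e-8))
  }
})

test_that("H2-rich gas favours ethanol, H2-poor gas acetate only", {
  rich <- solve_lexicographic_fba(net, c(co = 35, h2 = 70, co2 = 0))
  expect_gt(rich$mu, 0)
  expect_gt(rich$v_etoh, rich$v_ac)
  poor <- solve_lexicographic_fba(net, c(co = 35, h2 = 10, co2 = 0))
  expect_gt(poor$v_ac, 0)
  expect_lt(abs(poor$v_etoh), 1e-6)
})

test_that("uptake below the maintenance demand gives zero growth", {
  # with zero uptake the starving solution is identically zero
  s0 <- solve_lexicographic_fba(net, c(co = 0, h2 = 0, co2 = 0))
  expect_identical(s0$status, "starving")
  expect_identical(s0$mu, 0)
  expect_equal(c(s0$v_co, s0$v_h2, s0$v_co2, s0$v_etoh, s0$v_ac),
               rep(0, 5), tolerance = 1e-9)
  # with some gas but not enough for the full maintenance demand, cells
  # scavenge (acetate kinase ATP) without growing
  s1 <- solve_lexicographic_fba(net, c(co = 0.2, h2 = 0.2, co2 = 0))
  expect_identical(s1$status, "starving")
  expect_identical(s1$mu, 0)
  expect_lt(s1$v_co, -0.1)
  expect_gt(s1$v_ac, 0)
  # flux response is continuous across the growth/no-growth boundary:
  # maintenance-only feasibility needs 2(b_co + b_h2) = 8 * 0.45 / ...;
  # scan across the boundary and require no jumps in CO uptake
  bs <- seq(0.7, 1.1, by = 0.01)
  vco <- vapply(bs, function(b)
    solve_lexicographic_fba(net, c(co = b, h2 = b, co2 = 0))$v_co,
    numeric(1))
  expect_lt(max(abs(diff(vco))), 0.03)
})

test_that("reported exchanges are identical across repeats and permuted tails", {
  base <- solve_lexicographic_fba(net, c(co = 35, h2 = 70, co2 = 0))
  for (i in 1:10) {
    again <- solve_lexicographic_fba(net, c(co = 35, h2 = 70, co2 = 0))
    expect_identical(again$fluxes, base$fluxes)
  }
  tails <- list(c("co2", "acetate", "ethanol"), c("co2", "ethanol", "acetate"),
                c("acetate", "co2", "ethanol"), c("acetate", "ethanol", "co2"),
                c("ethanol", "co2", "acetate"), c("ethanol", "acetate", "co2"))
  for (cs in lex_oracle) {
    ref <- NULL
    for (tl in tails) {
      obj <- lexicographic_objectives(c("growth", "co", "h2", tl))
      sol <- solve_lexicographic_fba(net, cs$bounds, obj)
      v <- flux_vec(sol)
      if (is.null(ref)) ref <- v else expect_equal(v, ref, tolerance = 1e-6)
    }
  }
})

test_that("growth is monotone nondecreasing in each uptake bound", {
  grid <- expand.grid(co = c(0, 2, 10, 35), h2 = c(0, 2, 10, 70))
  mu <- mapply(function(co, h2)
    solve_lexicographic_fba(net, c(co = co, h2 = h2, co2 = 0))$mu,
    grid$co, grid$h2)
  mu <- matrix(mu, 4, 4)
  expect_true(all(diff(mu) >= -1e-9))      # along CO
  expect_true(all(t(diff(t(mu))) >= -1e-9))  # along H2
})

test_that("carbon is conserved at every returned solution", {
  # CO consumed = CO2 secreted + 2 (ethanol + acetate) + 20 mu
  for (b in list(c(co = 35, h2 = 70, co2 = 0), c(co = 35, h2 = 10, co2 = 0),
                 c(co = 12, h2 = 3, co2 = 0), c(co = 5, h2 = 10, co2 = 0))) {
    s <- solve_lexicographic_fba(net, b)
    expect_equal(-s$v_co, s$v_co2 + 2 * (s$v_etoh + s$v_ac) + 20 * s$mu,
                 tolerance = 1e-6)
  }
})

test_that("dissolved CO2 can be reassimilated through the CO2 exchange", {
  s <- solve_lexicographic_fba(net, c(co = 20, h2 = 70, co2 = 10))
  expect_lt(s$v_co2, 0)  # net uptake when carbon-limited and H2-rich
})

test_that("COBRA-JSON round trip preserves the network", {
  path <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(net, path)
  net2 <- load_metabolic_model(path, format = "json",
                               role_patterns = toy_patterns)
  expect_equal(as.matrix(net2$S)[net$metabolites, net$reactions],
               as.matrix(net$S))
  expect_equal(unname(net2$lower), unname(net$lower))
  expect_equal(unname(net2$upper), unname(net$upper))
  s1 <- solve_lexicographic_fba(net, c(co = 35, h2 = 70, co2 = 0))
  s2 <- solve_lexicographic_fba(net2, c(co = 35, h2 = 70, co2 = 0))
  expect_equal(flux_vec(s2), flux_vec(s1), tolerance = 1e-9)
})

test_that("the SBML reader parses a BiGG-style FBC file", {
  path <- system.file("extdata", "toy_wlp_synthetic.xml", package = "syncol")
  expect_true(nzchar(path))
  net2 <- load_metabolic_model(path, format = "sbml",
                               role_patterns = toy_patterns)
  expect_equal(sort(net2$metabolites), sort(net$metabolites))
  expect_equal(sort(net2$reactions), sort(net$reactions))
  s2 <- solve_lexicographic_fba(net2, c(co = 35, h2 = 70, co2 = 0))
  o <- lex_oracle$h2_rich
  expect_equal(flux_vec(s2),
               c(o$mu, o$v_co, o$v_h2, o$v_co2, o$v_etoh, o$v_ac),
               tolerance = 1e-6)
  expect_false(is.null(attr(net2, "checksum")))
})

test_that("missing roles raise a configuration error naming them", {
  bad <- toy_wlp_network()
  path <- withr::local_tempfile(fileext = ".json")
  bad$reactions[bad$reactions == "BIO"] <- "NOT_BIOMASS"
  names(bad$lower)[names(bad$lower) == "BIO"] <- "NOT_BIOMASS"
  names(bad$upper)[names(bad$upper) == "BIO"] <- "NOT_BIOMASS"
  colnames(bad$S)[colnames(bad$S) == "BIO"] <- "NOT_BIOMASS"
  bad$exchange[["growth"]] <- "NOT_BIOMASS"
  write_cobra_json(bad, path)
  expect_error(
    load_metabolic_model(path, format = "json", role_patterns = toy_patterns),
    class = "syncol_config_error", regexp = "growth")
})

test_that("parse failures raise a format error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("this is { not json", path)
  expect_error(load_metabolic_model(path, format = "json"),
               class = "syncol_format_error")
  expect_error(load_metabolic_model("no/such/file.xml"),
               class = "syncol_format_error")
})
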