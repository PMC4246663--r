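test_that("a pure-carbohydrate output on ammonia gives an assimilatory quotient of one", {
  cf <- core_fixture()
  carb <- composition_to_fluxes(
    cf$net, composition_table(c(starch_out = 0.4, suc_out = 0.2)), 1)
  cons <- leaf_constraints(carb, photon_flux = 60,
                           rubisco_cap = cf$params$rubisco_cap,
                           maintenance_atp = cf$params$maintenance_atp)
  thr <- find_min_photon_flux(cf$net, cons, lo = 1, hi = 100, tol = 1e-9)
  cons$photon_flux <- thr
  sol <- minimize_total_flux(cf$net, cons)
  # overall CO2 + H2O -> CH2O + O2: one O2 evolved per CO2 fixed
  expect_equal(assimilatory_quotient(sol, cf$net), 1, tolerance = 1e-8)
})

test_that("nitrate as sole nitrogen source strictly lowers the assimilatory quotient", {
  cf <- core_fixture()
  for (out in list(cf$biomass, cf$phloem)) {
    nh3 <- cf$cons(out)
    no3 <- nh3
    no3$closed <- "nh3_tx"
    t_nh3 <- find_min_photon_flux(cf$net, nh3, lo = 1, hi = 200, tol = 1e-8)
    t_no3 <- find_min_photon_flux(cf$net, no3, lo = 1, hi = 200, tol = 1e-8)
    nh3$photon_flux <- t_nh3
    no3$photon_flux <- t_no3
    aq_nh3 <- assimilatory_quotient(minimize_total_flux(cf$net, nh3), cf$net)
    aq_no3 <- assimilatory_quotient(minimize_total_flux(cf$net, no3), cf$net)
    expect_lt(aq_no3, aq_nh3)
    # extra reductant for nitrate reduction also raises the light threshold
    expect_gt(t_no3, t_nh3)
  }
})

test_that("the assimilatory quotient is scale invariant and flat across the photorespiratory range", {
  cf <- core_fixture()
  base <- cf$cons(cf$biomass, photon = 66)
  aq1 <- assimilatory_quotient(minimize_total_flux(cf$net, base), cf$net)

  # homogeneity: double the output rate, maintenance, cap and light together
  m2 <- build_core_leaf_model(core_leaf_params(
    biomass_rate = 2, maintenance_atp = 2 * cf$params$maintenance_atp,
    rubisco_cap = 2 * cf$params$rubisco_cap))
  b2 <- composition_to_fluxes(m2$net, m2$biomass, 2)
  cons2 <- leaf_constraints(b2, photon_flux = 132,
                            rubisco_cap = 2 * cf$params$rubisco_cap,
                            maintenance_atp = 2 * cf$params$maintenance_atp)
  aq2 <- assimilatory_quotient(minimize_total_flux(m2$net, cons2), m2$net)
  expect_equal(aq2, aq1, tolerance = 1e-8)

  # photorespiration rises across these lights, yet AQ does not move
  sc <- core_scan_1d()
  sols <- sc$solutions[, 1]
  pr <- vapply(sols, function(s) s$net_flux[["rubisco_o"]], numeric(1))
  nh3 <- vapply(sols, function(s) s$net_flux[["nh3_tx"]], numeric(1))
  in_pr <- which(pr > 1e-6 & nh3 > 1e-6)   # photorespiring, still on NH3
  expect_gte(length(in_pr), 2L)
  aqs <- vapply(sols[in_pr], assimilatory_quotient, numeric(1), net = cf$net)
  expect_lt(diff(range(aqs)), 1e-8)
})

test_that("active reaction counts use the scale-aware threshold", {
  toy <- atp_toy()
  sol <- minimize_total_flux(toy$net, toy$constraints)
  expect_equal(active_reaction_count(sol), 4L)

  zero <- structure(list(net_flux = c(a = 0, b = 0), status = "optimal",
                         photon_flux = 1),
                    class = "flux_solution")
  expect_equal(active_reaction_count(zero), 0L)
  expect_equal(active_reaction_count(
    structure(list(net_flux = c(a = 1e-3, b = 0), status = "optimal",
                   photon_flux = 1), class = "flux_solution")), 1L)
})

test_that("compartment exchanges reproduce the low/high-light organelle pattern", {
  cf <- core_fixture()
  thr <- analytic_min_photons(cf$params, "biomass", "nh3")
  low <- minimize_total_flux(cf$net, cf$cons(cf$biomass, thr * (1 + 1e-9)))
  high <- minimize_total_flux(cf$net, cf$cons(cf$biomass, 120))

  # low light: mitochondrial ATP synthase runs on chloroplast reductant,
  # exported as malate
  expect_gt(low$net_flux[["oxphos"]], 1e-6)
  chl_low <- compartment_exchange(low, cf$net, "chl")
  expect_lt(chl_low$fluxes[["Mal"]], -1e-9)

  # high light: the synthase is off and the chloroplast exports ATP, seen
  # as a positive ATP import on the cytosol side
  expect_lt(abs(high$net_flux[["oxphos"]]), 1e-6)
  cyt_high <- compartment_exchange(high, cf$net, "cyt")
  expect_gt(cyt_high$fluxes[["ATP"]], 1e-6)

  # steady state restricted to one compartment: species balances close
  for (comp in c("chl", "mit")) {
    comp_mets <- cf$net$metabolites$id[
      cf$net$metabolites$compartment == comp]
    N <- stoichiometric_matrix(cf$net)
    resid <- N[comp_mets, , drop = FALSE] %*% high$net_flux
    expect_lt(max(abs(resid)), 1e-8)
  }

  expect_error(compartment_exchange(high, cf$net, "vacuole"), "unknown")
})

test_that("nitrogen comes wholly from ammonia at minimal light and nitrate at high light", {
  cf <- core_fixture()
  thr <- analytic_min_photons(cf$params, "biomass", "nh3")
  low <- minimize_total_flux(cf$net, cf$cons(cf$biomass, thr * (1 + 1e-9)))
  sh_low <- nitrogen_source_shares(low, cf$net)
  expect_equal(unname(sh_low), c(1, 0), tolerance = 1e-6)

  high <- minimize_total_flux(cf$net, cf$cons(cf$biomass, 150))
  sh_high <- nitrogen_source_shares(high, cf$net)
  expect_equal(unname(sh_high), c(0, 1), tolerance = 1e-6)
  expect_equal(sum(sh_low), 1, tolerance = 1e-12)
  expect_equal(sum(sh_high), 1, tolerance = 1e-12)

  # no nitrogen uptake at all: undefined shares
  carb <- composition_to_fluxes(
    cf$net, composition_table(c(suc_out = 0.45)), 1)
  cons <- leaf_constraints(carb, photon_flux = 60,
                           maintenance_atp = cf$params$maintenance_atp,
                           rubisco_cap = cf$params$rubisco_cap)
  sol <- minimize_total_flux(cf$net, cons)
  expect_error(nitrogen_source_shares(sol, cf$net), "no nitrogen")
})
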