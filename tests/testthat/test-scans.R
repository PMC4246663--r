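test_that("bisection finds the energy toy's analytic threshold and validates its bracket", {
  toy <- atp_toy()
  thr <- find_min_photon_flux(toy$net, toy$constraints, lo = 0, hi = 10,
                              tol = 1e-6)
  expect_equal(thr, 3, tolerance = 1e-6)
  expect_error(find_min_photon_flux(toy$net, toy$constraints, lo = 5, hi = 10),
               "lower bracket feasible")
  expect_error(find_min_photon_flux(toy$net, toy$constraints, lo = 0, hi = 2),
               "upper bracket infeasible")
})

test_that("core-leaf minimal light matches the analytic manifest for both outputs", {
  cf <- core_fixture()
  for (case in list(list(out = cf$biomass, scen = "biomass"),
                    list(out = cf$phloem, scen = "phloem"))) {
    thr <- find_min_photon_flux(cf$net, cf$cons(case$out), lo = 1, hi = 100,
                                tol = 1e-6)
    expect_equal(thr, analytic_min_photons(cf$params, case$scen, "nh3"),
                 tolerance = 2e-6)
  }
  # the phloem mix demands less ATP per carbon, so it needs less light
  expect_lt(analytic_min_photons(cf$params, "phloem", "nh3"),
            analytic_min_photons(cf$params, "biomass", "nh3"))
})

test_that("light scans record infeasible low-light points and stay piecewise linear", {
  cf <- core_fixture()
  # grid straddling the threshold: infeasibility only at the low end
  grid <- c(40, 50, 57, 70, 100)
  sc <- scan_light(cf$net, cf$cons(cf$biomass), grid)
  status <- vapply(sc$solutions[, 1], function(s) s$status, character(1))
  expect_equal(status, c("infeasible", "infeasible", "optimal", "optimal",
                         "optimal"))

  sc_fine <- core_scan_1d()
  rg <- detect_regions(sc_fine, r = 0, min_change = 1)
  expect_lt(region_linearity(sc_fine, rg), 1e-6)
})

test_that("detected breakpoints are stable under grid refinement", {
  cf <- core_fixture()
  g1 <- light_grid(57, 300, 15)
  g2 <- light_grid(57, 300, 29)   # doubled density, same endpoints
  r1 <- detect_regions(scan_light(cf$net, cf$cons(cf$biomass), g1), r = 0)
  r2 <- detect_regions(scan_light(cf$net, cf$cons(cf$biomass), g2), r = 0)
  step <- diff(g1)
  for (bp in r1$breakpoints) {
    i <- findInterval(bp, g1)
    expect_true(any(abs(r2$breakpoints - bp) <= step[min(i, length(step))]))
  }
})

test_that("the region detector recovers a planted active-set change", {
  p <- c(1, 2, 3, 4)
  low <- c(a = 1, b = 1, c = 0)
  high <- c(a = 1, b = 0, c = 1)
  sc <- fake_scan(p, list(low, low, high, high))
  rg <- detect_regions(sc, r = 0, min_change = 1)
  expect_equal(length(rg$labels), 2L)
  expect_equal(rg$breakpoints, 2.5)

  # an unreachable change threshold collapses everything into one region
  rg1 <- detect_regions(sc, r = 0, min_change = Inf)
  expect_equal(rg1$labels, "A")
  expect_length(rg1$breakpoints, 0L)

  expect_error(detect_regions(fake_scan(p[1:2], list(low, low)), r = 0),
               "3 feasible")
})

test_that("an r grid of {0, 1} reproduces the two 1-D scans exactly", {
  cf <- core_fixture()
  grid <- light_grid(57, 150, 5)
  s2 <- scan_2d(cf$net, cf$cons(cf$biomass), grid, c(0, 1),
                cf$biomass, cf$phloem)
  s_b <- scan_light(cf$net, cf$cons(cf$biomass), grid)
  s_p <- scan_light(cf$net, cf$cons(cf$phloem), grid)
  for (i in seq_along(grid)) {
    expect_equal(s2$solutions[[i, 1]]$net_flux, s_b$solutions[[i, 1]]$net_flux)
    expect_equal(s2$solutions[[i, 2]]$net_flux, s_p$solutions[[i, 1]]$net_flux)
  }
})

test_that("net boundary carbon uptake is constant along the output transition", {
  cf <- core_fixture()
  s2 <- core_scan_2d()
  target <- cf$biomass$carbon_rate
  for (i in seq_along(s2$photon_values)) {
    for (k in seq_along(s2$r_values)) {
      s <- s2$solutions[[i, k]]
      if (s$status != "optimal") next
      co2 <- fluxscan:::boundary_uptake(s, cf$net, "CO2")
      expect_equal(co2, target, tolerance = 1e-8)
    }
  }
})

test_that("relative differences follow the defining ratio with guarded zero references", {
  p <- c(1, 2)
  mk <- function(a) c(v = a, w = 0)
  sc <- structure(list(
    photon_values = p, r_values = c(0, 0.5, 1),
    solutions = matrix(list(
      structure(list(net_flux = mk(1.15), status = "optimal", photon_flux = 1, r = 0), class = "flux_solution"),
      structure(list(net_flux = mk(2.30), status = "optimal", photon_flux = 2, r = 0), class = "flux_solution"),
      structure(list(net_flux = mk(1.00), status = "optimal", photon_flux = 1, r = 0.5), class = "flux_solution"),
      structure(list(net_flux = mk(2.00), status = "optimal", photon_flux = 2, r = 0.5), class = "flux_solution"),
      structure(list(net_flux = mk(0.90), status = "optimal", photon_flux = 1, r = 1), class = "flux_solution"),
      structure(list(net_flux = mk(1.80), status = "optimal", photon_flux = 2, r = 1), class = "flux_solution")),
      nrow = 2),
    reaction_ids = c("v", "w")), class = "scan_result")
  D <- relative_difference(sc, "v", reference_r = 0.5)
  expect_equal(D$D[1, ], c(`1` = 0.15, `0.5` = 0, `1` = -0.1),
               ignore_attr = TRUE)
  expect_equal(unname(D$D[, 2]), c(0, 0))
  # the zero-flux reaction has an undefined (NA) grid, not +-Inf
  Dw <- relative_difference(sc, "w", reference_r = 0.5)
  expect_true(all(is.na(Dw$D)))
  expect_error(relative_difference(sc, "v", reference_r = 0.25),
               "grid value")
})
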