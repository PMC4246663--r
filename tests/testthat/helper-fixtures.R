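# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Energy toy: photons convert 1:1 to ATP; the exported product costs 2 ATP
# per unit and maintenance drains 1 ATP, so with the export fixed at 1 the
# minimal feasible photon flux is 3. An overflow hydrolysis reaction absorbs
# photons beyond the requirement (the toy analog of the leaf model's
# substrate cycles), keeping feasibility monotone in light; it idles at the
# minimum, where exactly four reactions carry flux.
atp_toy <- function() {
  net <- parse_scrumpy(c(
    "photon_tx: x_Photon -> Photon",
    "photo: Photon -> ATP",
    "out: 2 ATP -> x_Out",
    "# @tags out: output_transporter",
    "maint: ATP ->",
    "# @tags maint: maintenance_atpase",
    "overflow: ATP ->"))
  scenario <- output_scenario(c(out = 1), r = 0, carbon_rate = 0)
  list(net = net,
       constraints = leaf_constraints(scenario, photon_flux = 3,
                                      maintenance_atp = 1))
}

# Core-leaf model at default parameters plus its derived scenarios.
core_fixture <- function() {
  cached("core", function() {
    m <- build_core_leaf_model()
    b <- composition_to_fluxes(m$net, m$biomass, m$params$biomass_rate)
    p <- scale_to_equal_carbon(
      composition_to_fluxes(m$net, m$phloem, 1), b)
    cons <- function(out, photon = 60)
      leaf_constraints(out, photon_flux = photon,
                       rubisco_cap = m$params$rubisco_cap,
                       maintenance_atp = m$params$maintenance_atp)
    list(net = m$net, params = m$params, biomass = b, phloem = p,
         cons = cons)
  })
}

# Shared 1-D biomass scan over the transition-rich light range.
core_scan_1d <- function() {
  cached("scan1d", function() {
    cf <- core_fixture()
    scan_light(cf$net, cf$cons(cf$biomass), light_grid(57, 300, 28))
  })
}

# Shared 2-D scan: 10 light points x 11 output fractions.
core_scan_2d <- function() {
  cached("scan2d", function() {
    cf <- core_fixture()
    scan_2d(cf$net, cf$cons(cf$biomass), light_grid(57, 250, 10),
            seq(0, 1, by = 0.1), cf$biomass, cf$phloem)
  })
}

# Minimal fake scan with planted flux patterns, for the region detector.
fake_scan <- function(photon_values, flux_rows, r = 0) {
  sols <- lapply(seq_along(photon_values), function(i) {
    structure(list(net_flux = flux_rows[[i]], objective = 0,
                   status = "optimal", photon_flux = photon_values[i],
                   r = r, residual = 0),
              class = "flux_solution")
  })
  structure(list(photon_values = photon_values, r_values = r,
                 solutions = matrix(sols, ncol = 1),
                 reaction_ids = names(flux_rows[[1]])),
            class = "scan_result")
}
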