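test_that("the default core-leaf model validates, balances and spans three compartments", {
  m <- build_core_leaf_model()
  expect_s3_class(m$net, "metabolic_network")
  expect_setequal(m$net$compartments, c("cyt", "chl", "mit"))
  expect_gte(length(m$net$reactions), 40L)
  # every tagged role the constraint layer needs is present
  for (tag in c("transporter", "cyclic_photophos", "noncyclic_photophos",
                "rubisco_carboxylase", "rubisco_oxygenase",
                "maintenance_atpase", "output_transporter"))
    expect_gte(length(tagged_reactions(m$net, tag)), 1L)
  # phloem mix is the nitrogen-rich one
  el <- fluxscan:::core_leaf_elements()
  nc <- function(tab) {
    w <- tab$entries
    sp <- vapply(names(w), function(id)
      fluxscan:::species_base(names(m$net$reactions[[id]]$stoich)[
        m$net$reactions[[id]]$stoich > 0]), character(1))
    i <- match(sp, el$species)
    sum(w * el$nitrogen[i]) / sum(w * el$carbon[i])
  }
  expect_gt(nc(m$phloem), nc(m$biomass))
})

test_that("the element audit rejects an unbalanced lumped reaction", {
  el <- fluxscan:::core_leaf_elements()
  bad <- list(leak = list(stoich = c(CO2_chl = -1), reversible = FALSE))
  expect_error(fluxscan:::audit_element_balance(bad, el),
               "leak.*carbon|carbon.*leak")
  expect_error(core_leaf_params(phloem_aa = 0.001), "N:C")
})

test_that("the light scan of the default model walks through the expected regimes in order", {
  cf <- core_fixture()
  sc <- core_scan_1d()
  sols <- sc$solutions[, 1]
  p <- sc$photon_values
  get <- function(id) vapply(sols, function(s) s$net_flux[[id]], numeric(1))
  oxphos <- get("oxphos")
  pr <- get("rubisco_o")
  tol <- 1e-6

  # mitochondrial ATP synthase: active at the lowest feasible light, then off
  expect_gt(oxphos[1], tol)
  mito_off <- p[which(oxphos <= tol)[1]]
  expect_false(is.na(mito_off))

  # photorespiration onset at or after the mitochondrial switch-off
  pr_on <- p[which(pr > tol)[1]]
  expect_gte(pr_on, mito_off - 1e-9)

  # dissipation begins once the rubisco cap binds
  diss <- vapply(seq_along(sols), function(i)
    sum(photon_excess_diagnostics(sols[[i]], cf$net)$energy_dissipated),
    numeric(1))
  diss_on_i <- which(diss > tol)[1]
  expect_false(is.na(diss_on_i))
  expect_gte(p[diss_on_i], pr_on)
  rub_tot <- get("rubisco_c")[diss_on_i] + pr[diss_on_i]
  expect_equal(rub_tot, cf$params$rubisco_cap, tolerance = 1e-6)

  # at least four active-set breakpoints along the slice
  rg <- detect_regions(sc, r = 0, min_change = 1)
  expect_gte(length(rg$breakpoints), 4L)
})

test_that("the nitrate transition starts at lower light for phloem than for biomass", {
  cf <- core_fixture()
  grid <- light_grid(70, 85, 16)
  onset <- function(out) {
    cons <- cf$cons(out)
    sc <- scan_light(cf$net, cons, grid)
    no3 <- vapply(sc$solutions[, 1], function(s) s$net_flux[["no3_tx"]],
                  numeric(1))
    grid[which(no3 > 1e-6)[1]]
  }
  expect_lt(onset(cf$phloem), onset(cf$biomass))
})

test_that("random branched networks are deterministic and honor their shortcut structure", {
  a <- random_branched_network(7, 6L)
  b <- random_branched_network(7, 6L)
  expect_identical(serialize_scrumpy(a$net), serialize_scrumpy(b$net))
  expect_equal(brute_force_min_flux(a$net, a$constraints)$objective,
               brute_force_min_flux(b$net, b$constraints)$objective)

  # dropping a shortcut can only preserve or raise the optimum
  for (seed in 1:12) {
    f <- random_branched_network(seed, 7L)
    shorts <- grep("^short", names(f$net$reactions), value = TRUE)
    if (length(shorts) == 0L) next
    with_all <- brute_force_min_flux(f$net, f$constraints)
    pruned <- f$net
    pruned$reactions[[shorts[1]]] <- NULL
    without <- brute_force_min_flux(pruned, f$constraints)
    if (with_all$status == "optimal" && without$status == "optimal")
      expect_gte(without$objective, with_all$objective - 1e-12)
  }
})

test_that("the fixture writer emits a loadable model whose manifest matches the analytics", {
  dir <- withr::local_tempdir()
  manifest <- write_core_leaf_fixture(dir)
  expect_setequal(list.files(dir),
                  c("core_leaf.spy", "elements.tsv", "biomass.tsv",
                    "phloem.tsv", "manifest.json"))
  net <- load_model(file.path(dir, "core_leaf.spy"), "scrumpy",
                    elements = file.path(dir, "elements.tsv"))
  ref <- build_core_leaf_model()$net
  expect_setequal(names(net$reactions), names(ref$reactions))
  biomass <- read_composition(file.path(dir, "biomass.tsv"), "biomass")
  b <- composition_to_fluxes(net, biomass, 1)
  expect_equal(b$carbon_rate, 5.4)

  stored <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  p <- core_leaf_params()
  for (nm in names(stored$analytic_min_photons)) {
    parts <- strsplit(nm, "_")[[1]]
    expect_equal(stored$analytic_min_photons[[nm]],
                 analytic_min_photons(p, parts[1], parts[2]),
                 tolerance = 1e-12)
  }
})
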