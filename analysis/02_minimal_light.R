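#!/usr/bin/env Rscript
# Locate the minimal feasible photon flux for the pure biomass and pure
# phloem outputs by bisection on LP feasibility, under both nitrogen
# sources, and compare with the closed-form thresholds in the manifest.

library(fluxscan)

dir.create("results", showWarnings = FALSE)

model <- build_core_leaf_model()
net <- model$net
p <- model$params
biomass <- composition_to_fluxes(net, model$biomass, p$biomass_rate)
phloem <- scale_to_equal_carbon(
  composition_to_fluxes(net, model$phloem, 1), biomass)

cons <- function(out, closed = character())
  leaf_constraints(out, photon_flux = 1, rubisco_cap = p$rubisco_cap,
                   maintenance_atp = p$maintenance_atp, closed = closed)

rows <- list()
for (scen in c("biomass", "phloem")) {
  out <- if (scen == "biomass") biomass else phloem
  for (nsrc in c("nh3", "no3")) {
    closed <- if (nsrc == "no3") "nh3_tx" else character()
    thr <- find_min_photon_flux(net, cons(out, closed),
                                lo = 1, hi = 200, tol = 1e-6)
    ana <- analytic_min_photons(p, scen, nsrc)
    rows[[paste(scen, nsrc, sep = "_")]] <-
      data.frame(scenario = scen, n_source = toupper(nsrc),
                 bisection = thr, analytic = ana,
                 abs_error = abs(thr - ana))
    cat(sprintf("%-8s %-4s: bisection %.6f  analytic %.6f  |err| %.2e\n",
                scen, toupper(nsrc), thr, ana, abs(thr - ana)))
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/minimal_light.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nfindings:\n")
cat(sprintf(" - phloem sap needs %.3f photon units vs %.3f for biomass:\n",
            tab["phloem_nh3", "bisection"], tab["biomass_nh3", "bisection"]),
    "  the amino-acid-rich mix is cheaper in ATP per carbon, so it can be\n",
    "  produced at slightly lower light\n")
cat(sprintf(" - forcing nitrate raises both thresholds (to %.3f / %.3f):\n",
            tab["biomass_no3", "bisection"], tab["phloem_no3", "bisection"]),
    "  reducing NO3 to NH3 costs extra reductant\n")
cat("table written to results/minimal_light.tsv\n")
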