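#' Parameters of the synthetic core-leaf model
#'
#' A lumped, three-compartment (cytosol / chloroplast / mitochondrion)
#' mesophyll network: non-cyclic and cyclic photophosphorylation, a lumped
#' Calvin cycle with separate rubisco carboxylase and oxygenase branches and
#' a multi-step photorespiratory salvage route, starch and sucrose synthesis
#' (each with its degradation partner, forming the substrate cycles that
#' dissipate excess energy), a malate-oxaloacetate shuttle across both
#' organelle membranes, pyruvate oxidation / TCA / oxidative phosphorylation,
#' NH3 and NO3 assimilation (NO3 requiring extra reductant), a maintenance
#' ATPase, and export transporters for a biomass-like and a phloem-like
#' output mix with a higher N:C ratio in the phloem.
#'
#' Defaults use textbook lumped stoichiometries (4 photons per NADPH with
#' one coupled ATP; 2 photons per cyclic ATP; Calvin cost 2 NADPH + 3 ATP
#' per CO2; 2.5 ATP per mitochondrial NADH; 4 NADPH per NO3 reduced, i.e.
#' 8 electrons) and are chosen so that, over a 100-fold light range, the
#' scan passes through all qualitative regimes: mitochondrial ATP supply at
#' low light, its decline, the NH3-to-NO3 switch, photorespiration growth,
#' and substrate-cycle dissipation once the rubisco cap binds.
#'
#' @param photons_per_nadph photons consumed per NADPH by non-cyclic
#'   photophosphorylation.
#' @param atp_per_nadph_noncyclic ATP made per NADPH by the non-cyclic route.
#' @param photons_per_atp_cyclic photons per ATP by cyclic
#'   photophosphorylation.
#' @param nadph_per_co2_calvin,atp_per_co2_calvin Calvin-cycle cost per CO2.
#' @param oxygenase_atp,oxygenase_salvage_atp ATP cost structure of the
#'   photorespiratory branch (oxygenase step and cytosolic salvage step).
#' @param nadph_per_no3 extra reductant to reduce NO3 to NH3 (NADPH per N).
#' @param atp_per_mito_nadh P/O-type yield of oxidative phosphorylation.
#' @param atp_per_starch,atp_per_sucrose,atp_per_aa synthesis ATP costs.
#' @param maintenance_atp fixed maintenance ATPase flux (model flux units).
#' @param rubisco_cap cap on carboxylase + oxygenase flux.
#' @param biomass_rate absolute rate multiplying the biomass composition.
#' @param biomass_starch,biomass_suc,biomass_aa relative molar export rates
#'   of the biomass components.
#' @param phloem_suc,phloem_aa relative molar export rates of the phloem
#'   components (amino-acid rich: N:C above the biomass mix).
#' @return object of class `core_leaf_params`.
#' @export
core_leaf_params <- function(photons_per_nadph = 4,
                             atp_per_nadph_noncyclic = 1,
                             photons_per_atp_cyclic = 2,
                             nadph_per_co2_calvin = 2,
                             atp_per_co2_calvin = 3,
                             oxygenase_atp = 0,
                             oxygenase_salvage_atp = 1,
                             nadph_per_no3 = 4,
                             atp_per_mito_nadh = 2.5,
                             atp_per_starch = 1,
                             atp_per_sucrose = 1,
                             atp_per_aa = 1,
                             maintenance_atp = 2,
                             rubisco_cap = 8,
                             biomass_rate = 1,
                             biomass_starch = 0.4,
                             biomass_suc = 0.2,
                             biomass_aa = 0.2,
                             phloem_suc = 1,
                             phloem_aa = 1) {
  p <- as.list(environment())
  pos <- c("photons_per_nadph", "atp_per_nadph_noncyclic",
           "photons_per_atp_cyclic", "nadph_per_co2_calvin",
           "atp_per_co2_calvin", "nadph_per_no3", "atp_per_mito_nadh",
           "rubisco_cap", "biomass_rate")
  for (nm in pos) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop(nm, " must be positive")
  nonneg <- c("oxygenase_atp", "oxygenase_salvage_atp", "atp_per_starch",
              "atp_per_sucrose", "atp_per_aa", "maintenance_atp",
              "biomass_starch", "biomass_suc", "biomass_aa",
              "phloem_suc", "phloem_aa")
  for (nm in nonneg) if (!is.finite(p[[nm]]) || p[[nm]] < 0)
    stop(nm, " must be non-negative")
  el <- core_leaf_elements()
  cn <- function(w, sp) sum(w * el$carbon[match(sp, el$species)])
  nn <- function(w, sp) sum(w * el$nitrogen[match(sp, el$species)])
  b_c <- cn(c(p$biomass_starch, p$biomass_suc, p$biomass_aa),
            c("Starch", "Suc", "AA"))
  b_n <- nn(c(p$biomass_starch, p$biomass_suc, p$biomass_aa),
            c("Starch", "Suc", "AA"))
  p_c <- cn(c(p$phloem_suc, p$phloem_aa), c("Suc", "AA"))
  p_n <- nn(c(p$phloem_suc, p$phloem_aa), c("Suc", "AA"))
  if (b_c <= 0 || p_c <= 0) stop("both output mixes must export carbon")
  if (p_n / p_c <= b_n / b_c)
    stop("phloem N:C ratio (", format(p_n / p_c),
         ") must exceed the biomass N:C ratio (", format(b_n / b_c), ")")
  structure(p, class = "core_leaf_params")
}

## Element (C, N) and internal oxygen bookkeeping for the lumped species.
## Oxygen is used only by the builder's balance audit; the network stores C
## and N. Energy carriers are conserved-moiety pairs (ATP means ADP -> ATP)
## and carry no atoms.
core_leaf_elements <- function() {
  data.frame(
    species = c("Photon", "CO2", "O2", "H2O", "NH3", "NO3",
                "ATP", "NADPH", "NADH",
                "TP", "Glyc", "Mal", "OAA", "Pyr", "Starch", "Suc", "AA"),
    carbon = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 3, 1, 4, 4, 3, 6, 12, 3),
    nitrogen = c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    oxygen = c(0, 2, 2, 1, 0, 3, 0, 0, 0, 3, 3, 5, 5, 3, 5, 11, 2),
    stringsAsFactors = FALSE)
}

#' Build the synthetic core-leaf model
#'
#' Constructs the lumped three-compartment network described in
#' [core_leaf_params()], audits carbon / nitrogen / oxygen balance of every
#' non-boundary reaction at the lumped level, and returns it together with
#' the biomass and phloem composition tables.
#'
#' @param params a `core_leaf_params` (default: `core_leaf_params()`).
#' @return list with `net` (a `metabolic_network` with all role tags set),
#'   `biomass` and `phloem` (`composition_table`s), and `params`.
#' @export
build_core_leaf_model <- function(params = core_leaf_params()) {
  stopifnot(inherits(params, "core_leaf_params"))
  p <- params
  rx <- list()
  add <- function(id, stoich, reversible = FALSE, tags = character()) {
    rx[[id]] <<- list(stoich = stoich, reversible = reversible, tags = tags)
  }
  st <- function(...) {
    v <- c(...)
    v[v != 0]
  }

  ## --- boundary transporters ------------------------------------------
  add("photon_tx", st(x_Photon = -1, Photon_chl = 1), tags = "transporter")
  add("co2_tx", st(x_CO2 = -1, CO2_cyt = 1), reversible = TRUE,
      tags = "transporter")
  add("o2_tx", st(x_O2 = -1, O2_cyt = 1), reversible = TRUE,
      tags = "transporter")
  add("h2o_tx", st(x_H2O = -1, H2O_cyt = 1), reversible = TRUE,
      tags = "transporter")
  add("nh3_tx", st(x_NH3 = -1, NH3_cyt = 1), tags = "transporter")
  add("no3_tx", st(x_NO3 = -1, NO3_cyt = 1), tags = "transporter")

  ## --- intracellular transporters -------------------------------------
  add("co2_chl_tx", st(CO2_cyt = -1, CO2_chl = 1), reversible = TRUE,
      tags = "transporter")
  add("o2_chl_tx", st(O2_cyt = -1, O2_chl = 1), reversible = TRUE,
      tags = "transporter")
  add("h2o_chl_tx", st(H2O_cyt = -1, H2O_chl = 1), reversible = TRUE,
      tags = "transporter")
  add("co2_mit_tx", st(CO2_cyt = -1, CO2_mit = 1), reversible = TRUE,
      tags = "transporter")
  add("o2_mit_tx", st(O2_cyt = -1, O2_mit = 1), reversible = TRUE,
      tags = "transporter")
  add("h2o_mit_tx", st(H2O_cyt = -1, H2O_mit = 1), reversible = TRUE,
      tags = "transporter")
  add("tp_chl_tx", st(TP_chl = -1, TP_cyt = 1), reversible = TRUE,
      tags = "transporter")
  add("glyc_chl_tx", st(Glyc_chl = -1, Glyc_cyt = 1), tags = "transporter")
  add("mal_chl_tx", st(Mal_chl = -1, Mal_cyt = 1), reversible = TRUE,
      tags = "transporter")
  add("oaa_chl_tx", st(OAA_cyt = -1, OAA_chl = 1), reversible = TRUE,
      tags = "transporter")
  add("mal_mit_tx", st(Mal_cyt = -1, Mal_mit = 1), reversible = TRUE,
      tags = "transporter")
  add("oaa_mit_tx", st(OAA_mit = -1, OAA_cyt = 1), reversible = TRUE,
      tags = "transporter")
  add("pyr_mit_tx", st(Pyr_cyt = -1, Pyr_mit = 1), tags = "transporter")
  add("atp_chl_tx", st(ATP_chl = -1, ATP_cyt = 1), tags = "transporter")
  add("atp_mit_tx", st(ATP_mit = -1, ATP_cyt = 1), tags = "transporter")
  add("no3_chl_tx", st(NO3_cyt = -1, NO3_chl = 1), tags = "transporter")
  add("nh3_chl_tx", st(NH3_chl = -1, NH3_cyt = 1), tags = "transporter")

  ## --- chloroplast -----------------------------------------------------
  add("noncyc_photo",
      st(Photon_chl = -p$photons_per_nadph, H2O_chl = -1,
         NADPH_chl = 1, ATP_chl = p$atp_per_nadph_noncyclic, O2_chl = 0.5),
      tags = "noncyclic_photophos")
  add("cyc_photo",
      st(Photon_chl = -p$photons_per_atp_cyclic, ATP_chl = 1),
      tags = "cyclic_photophos")
  add("rubisco_c",
      st(CO2_chl = -1, NADPH_chl = -p$nadph_per_co2_calvin,
         ATP_chl = -p$atp_per_co2_calvin, TP_chl = 1 / 3, H2O_chl = 1),
      tags = "rubisco_carboxylase")
  add("rubisco_o",
      st(TP_chl = -1 / 3, O2_chl = -1, ATP_chl = -p$oxygenase_atp,
         Glyc_chl = 1),
      tags = "rubisco_oxygenase")
  add("starch_syn",
      st(TP_chl = -2, ATP_chl = -p$atp_per_starch,
         Starch_chl = 1, H2O_chl = 1))
  add("starch_deg", st(Starch_chl = -1, H2O_chl = -1, TP_chl = 2))
  add("mdh_chl", st(OAA_chl = -1, NADPH_chl = -1, Mal_chl = 1))
  add("no3_red",
      st(NO3_chl = -1, NADPH_chl = -p$nadph_per_no3,
         NH3_chl = 1, H2O_chl = 3))

  ## --- cytosol ---------------------------------------------------------
  add("glycolysis", st(TP_cyt = -1, Pyr_cyt = 1, NADH_cyt = 1, ATP_cyt = 2))
  add("mdh_cyt", st(Mal_cyt = -1, OAA_cyt = 1, NADH_cyt = 1),
      reversible = TRUE)
  add("suc_syn",
      st(TP_cyt = -4, ATP_cyt = -p$atp_per_sucrose, Suc_cyt = 1, H2O_cyt = 1))
  add("invertase", st(Suc_cyt = -1, H2O_cyt = -1, TP_cyt = 4))
  add("aa_syn",
      st(Pyr_cyt = -1, NH3_cyt = -1, NADH_cyt = -1, ATP_cyt = -p$atp_per_aa,
         AA_cyt = 1, H2O_cyt = 1))
  add("pr_salvage",
      st(Glyc_cyt = -1, ATP_cyt = -p$oxygenase_salvage_atp,
         CO2_cyt = 1, H2O_cyt = 1))
  add("maint_atpase", st(ATP_cyt = -1), tags = "maintenance_atpase")

  ## --- mitochondrion ---------------------------------------------------
  add("pyr_ox", st(Pyr_mit = -1, H2O_mit = -3, CO2_mit = 3, NADH_mit = 5))
  add("mdh_mit", st(Mal_mit = -1, OAA_mit = 1, NADH_mit = 1),
      reversible = TRUE)
  add("oxphos",
      st(NADH_mit = -1, O2_mit = -0.5, ATP_mit = p$atp_per_mito_nadh,
         H2O_mit = 1))
  ## alternative oxidase: uncoupled NADH oxidation, the reductant overflow
  ## valve plant mitochondria use under excess light
  add("aox", st(NADH_mit = -1, O2_mit = -0.5, H2O_mit = 1))

  ## --- output transporters --------------------------------------------
  add("starch_out", st(Starch_chl = -1, x_Starch = 1),
      tags = c("transporter", "output_transporter"))
  add("suc_out", st(Suc_cyt = -1, x_Suc = 1),
      tags = c("transporter", "output_transporter"))
  add("aa_out", st(AA_cyt = -1, x_AA = 1),
      tags = c("transporter", "output_transporter"))

  el <- core_leaf_elements()
  audit_element_balance(rx, el)
  net <- metabolic_network(rx, elements = el[c("species", "carbon", "nitrogen")])

  biomass <- composition_table(
    c(starch_out = p$biomass_starch, suc_out = p$biomass_suc,
      aa_out = p$biomass_aa), label = "biomass")
  phloem <- composition_table(
    c(suc_out = p$phloem_suc, aa_out = p$phloem_aa), label = "phloem")
  list(net = net, biomass = biomass, phloem = phloem, params = params)
}

## Carbon, nitrogen and oxygen must balance in every reaction (transporters
## move one species, so they balance trivially; the ATP-consuming steps
## balance because the energy carriers are atom-free conserved moieties).
audit_element_balance <- function(rx, el) {
  for (id in names(rx)) {
    stoich <- rx[[id]]$stoich
    base <- species_base(names(stoich))
    i <- match(base, el$species)
    if (anyNA(i)) stop("reaction '", id, "' uses species without element ",
                       "data: ", base[is.na(i)][1L])
    for (elem in c("carbon", "nitrogen", "oxygen")) {
      bal <- sum(stoich * el[[elem]][i])
      if (abs(bal) > 1e-9)
        stop("reaction '", id, "' is ", elem, "-unbalanced by ", format(bal))
    }
  }
  invisible(TRUE)
}

#' Analytic minimal photon flux for a pure output scenario
#'
#' Closed-form threshold, independent of the linear programme, derived from
#' the lumped pathway costs at the photon-limited optimum: all carbon is
#' fixed once by the carboxylase (2 NADPH per CO2 at defaults, so NADPH
#' demand is proportional to exported carbon); cytosolic ATP demand is met
#' by the malate-oxaloacetate shuttle into mitochondrial oxidative
#' phosphorylation (the photon-cheapest cytosolic ATP source whenever
#' `atp_per_mito_nadh * photons_per_atp_cyclic > photons_per_nadph`); and
#' any remaining chloroplast ATP gap is closed by cyclic
#' photophosphorylation. NH3 is the nitrogen source at threshold unless NO3
#' is forced, in which case each N adds `nadph_per_no3` NADPH.
#'
#' @param params a `core_leaf_params`.
#' @param scenario `"biomass"` or `"phloem"` (phloem is equal-carbon scaled
#'   to the biomass mix at `biomass_rate`).
#' @param n_source `"nh3"` or `"no3"`.
#' @return the threshold photon flux.
#' @export
analytic_min_photons <- function(params, scenario = c("biomass", "phloem"),
                                 n_source = c("nh3", "no3")) {
  scenario <- match.arg(scenario)
  n_source <- match.arg(n_source)
  p <- params
  el <- core_leaf_elements()
  atoms <- function(sp, elem) el[[elem]][match(sp, el$species)]

  comp <- if (scenario == "biomass") {
    c(Starch = p$biomass_starch, Suc = p$biomass_suc, AA = p$biomass_aa) *
      p$biomass_rate
  } else {
    raw <- c(Suc = p$phloem_suc, AA = p$phloem_aa)
    b_c <- sum(c(p$biomass_starch, p$biomass_suc, p$biomass_aa) *
                 atoms(c("Starch", "Suc", "AA"), "carbon")) * p$biomass_rate
    raw * (b_c / sum(raw * atoms(names(raw), "carbon")))
  }
  carbon <- sum(comp * atoms(names(comp), "carbon"))
  n_atoms <- sum(comp * atoms(names(comp), "nitrogen"))

  getc <- function(nm) {
    v <- comp[nm]
    if (is.na(v)) 0 else unname(v)
  }

  ## NADPH demand: Calvin fixation of all exported carbon (+ NO3 reduction)
  d_nadph <- p$nadph_per_co2_calvin * carbon +
    if (n_source == "no3") p$nadph_per_no3 * n_atoms else 0

  ## chloroplast ATP demand: Calvin + starch synthesis
  a_chl <- p$atp_per_co2_calvin * carbon +
    p$atp_per_starch * getc("Starch")

  ## net cytosolic ATP demand: maintenance + sucrose synthesis + amino-acid
  ## synthesis, minus the glycolytic ATP gained making pyruvate for AA
  a_cyt <- p$maintenance_atp + p$atp_per_sucrose * getc("Suc") +
    (p$atp_per_aa - 2) * getc("AA")   # glycolysis TP -> Pyr yields 2 ATP

  a_nc <- p$atp_per_nadph_noncyclic
  theta <- p$atp_per_mito_nadh
  ## Shuttle NADPH (s) covers cytosolic ATP whenever the chloroplast cannot
  ## (shuttle is photon-cheaper than the cyclic route when
  ## theta * photons_per_atp_cyclic > photons_per_nadph); a remaining
  ## chloroplast ATP gap is closed by cyclic photophosphorylation, and a
  ## chloroplast ATP surplus exports to the cytosol, displacing shuttle.
  s1 <- max(0, a_cyt) / theta
  if (a_chl >= a_nc * (d_nadph + s1)) {
    gap <- a_chl - a_nc * (d_nadph + s1)
    return(p$photons_per_nadph * (d_nadph + s1) +
             p$photons_per_atp_cyclic * gap)
  }
  s2 <- (max(0, a_cyt) + a_chl - a_nc * d_nadph) / (a_nc + theta)
  if (s2 > 0) return(p$photons_per_nadph * (d_nadph + s2))
  p$photons_per_nadph * d_nadph
}

#' Write the core-leaf fixture set to a directory
#'
#' Emits the model in the ScrumPy-style dialect (`core_leaf.spy`), the
#' element side table (`elements.tsv`), both composition tables
#' (`biomass.tsv`, `phloem.tsv`) and a manifest (`manifest.json`) holding
#' the parameter values and the analytic minimal-light thresholds for the
#' pure scenarios under both nitrogen sources.
#'
#' @param dir output directory (created if missing).
#' @param params a `core_leaf_params`.
#' @return invisibly, the manifest as a list.
#' @export
write_core_leaf_fixture <- function(dir, params = core_leaf_params()) {
  model <- build_core_leaf_model(params)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(serialize_scrumpy(model$net), file.path(dir, "core_leaf.spy"))
  el <- core_leaf_elements()
  utils::write.table(
    data.frame(metabolite_id = el$species, carbon_atoms = el$carbon,
               nitrogen_atoms = el$nitrogen),
    file.path(dir, "elements.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (nm in c("biomass", "phloem")) {
    tab <- model[[nm]]
    utils::write.table(
      data.frame(transporter_id = names(tab$entries),
                 relative_rate = unname(tab$entries)),
      file.path(dir, paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  manifest <- list(
    params = unclass(params),
    analytic_min_photons = list(
      biomass_nh3 = analytic_min_photons(params, "biomass", "nh3"),
      phloem_nh3 = analytic_min_photons(params, "phloem", "nh3"),
      biomass_no3 = analytic_min_photons(params, "biomass", "no3"),
      phloem_no3 = analytic_min_photons(params, "phloem", "no3")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
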