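{
  "params": {
    "photons_per_nadph": 4,
    "atp_per_nadph_noncyclic": 1,
    "photons_per_atp_cyclic": 2,
    "nadph_per_co2_calvin": 2,
    "atp_per_co2_calvin": 3,
    "oxygenase_atp": 0,
    "oxygenase_salvage_atp": 1,
    "nadph_per_no3": 4,
    "atp_per_mito_nadh": 2.5,
    "atp_per_starch": 1,
    "atp_per_sucrose": 1,
    "atp_per_aa": 1,
    "maintenance_atp": 2,
    "rubisco_cap": 8,
    "biomass_rate": 1,
    "biomass_starch": 0.4,
    "biomass_suc": 0.2,
    "biomass_aa": 0.2,
    "phloem_suc": 1,
    "phloem_aa": 1
  },
  "analytic_min_photons": {
    "biomass_nh3": 56.4,
    "phloem_nh3": 55.6,
    "biomass_no3": 58,
    "phloem_no3": 58.48
  }
}
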