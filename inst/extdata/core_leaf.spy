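photon_tx: x_Photon -> Photon_chl
co2_tx: x_CO2 <> CO2_cyt
o2_tx: x_O2 <> O2_cyt
h2o_tx: x_H2O <> H2O_cyt
nh3_tx: x_NH3 -> NH3_cyt
no3_tx: x_NO3 -> NO3_cyt
co2_chl_tx: CO2_cyt <> CO2_chl
# @tags co2_chl_tx: transporter
o2_chl_tx: O2_cyt <> O2_chl
# @tags o2_chl_tx: transporter
h2o_chl_tx: H2O_cyt <> H2O_chl
# @tags h2o_chl_tx: transporter
co2_mit_tx: CO2_cyt <> CO2_mit
# @tags co2_mit_tx: transporter
o2_mit_tx: O2_cyt <> O2_mit
# @tags o2_mit_tx: transporter
h2o_mit_tx: H2O_cyt <> H2O_mit
# @tags h2o_mit_tx: transporter
tp_chl_tx: TP_chl <> TP_cyt
# @tags tp_chl_tx: transporter
glyc_chl_tx: Glyc_chl -> Glyc_cyt
# @tags glyc_chl_tx: transporter
mal_chl_tx: Mal_chl <> Mal_cyt
# @tags mal_chl_tx: transporter
oaa_chl_tx: OAA_cyt <> OAA_chl
# @tags oaa_chl_tx: transporter
mal_mit_tx: Mal_cyt <> Mal_mit
# @tags mal_mit_tx: transporter
oaa_mit_tx: OAA_mit <> OAA_cyt
# @tags oaa_mit_tx: transporter
pyr_mit_tx: Pyr_cyt -> Pyr_mit
# @tags pyr_mit_tx: transporter
atp_chl_tx: ATP_chl -> ATP_cyt
# @tags atp_chl_tx: transporter
atp_mit_tx: ATP_mit -> ATP_cyt
# @tags atp_mit_tx: transporter
no3_chl_tx: NO3_cyt -> NO3_chl
# @tags no3_chl_tx: transporter
nh3_chl_tx: NH3_chl -> NH3_cyt
# @tags nh3_chl_tx: transporter
noncyc_photo: 4 Photon_chl + H2O_chl -> NADPH_chl + ATP_chl + 0.5 O2_chl
# @tags noncyc_photo: noncyclic_photophos
cyc_photo: 2 Photon_chl -> ATP_chl
# @tags cyc_photo: cyclic_photophos
rubisco_c: CO2_chl + 2 NADPH_chl + 3 ATP_chl -> 0.33333333333333331 TP_chl + H2O_chl
# @tags rubisco_c: rubisco_carboxylase
rubisco_o: 0.33333333333333331 TP_chl + O2_chl -> Glyc_chl
# @tags rubisco_o: rubisco_oxygenase
starch_syn: 2 TP_chl + ATP_chl -> Starch_chl + H2O_chl
starch_deg: Starch_chl + H2O_chl -> 2 TP_chl
mdh_chl: OAA_chl + NADPH_chl -> Mal_chl
no3_red: NO3_chl + 4 NADPH_chl -> NH3_chl + 3 H2O_chl
glycolysis: TP_cyt -> Pyr_cyt + NADH_cyt + 2 ATP_cyt
mdh_cyt: Mal_cyt <> OAA_cyt + NADH_cyt
suc_syn: 4 TP_cyt + ATP_cyt -> Suc_cyt + H2O_cyt
invertase: Suc_cyt + H2O_cyt -> 4 TP_cyt
aa_syn: Pyr_cyt + NH3_cyt + NADH_cyt + ATP_cyt -> AA_cyt + H2O_cyt
pr_salvage: Glyc_cyt + ATP_cyt -> CO2_cyt + H2O_cyt
maint_atpase: ATP_cyt -> 
# @tags maint_atpase: maintenance_atpase
pyr_ox: Pyr_mit + 3 H2O_mit -> 3 CO2_mit + 5 NADH_mit
mdh_mit: Mal_mit <> OAA_mit + NADH_mit
oxphos: NADH_mit + 0.5 O2_mit -> 2.5 ATP_mit + H2O_mit
aox: NADH_mit + 0.5 O2_mit -> H2O_mit
starch_out: Starch_chl -> x_Starch
# @tags starch_out: output_transporter
suc_out: Suc_cyt -> x_Suc
# @tags suc_out: output_transporter
aa_out: AA_cyt -> x_AA
# @tags aa_out: output_transporter
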