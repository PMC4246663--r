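metabolite_id	carbon_atoms	nitrogen_atoms
Photon	0	0
CO2	1	0
O2	0	0
H2O	0	0
NH3	0	1
NO3	0	1
ATP	0	0
NADPH	0	0
NADH	0	0
TP	3	0
Glyc	1	0
Mal	4	0
OAA	4	0
Pyr	3	0
Starch	6	0
Suc	12	0
AA	3	1
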