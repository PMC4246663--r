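transporter_id	relative_rate
starch_out	0.4
suc_out	0.2
aa_out	0.2
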