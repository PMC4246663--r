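transporter_id	relative_rate
suc_out	1
aa_out	1
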