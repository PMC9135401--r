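# Fatty-acid metabolism module (KEGG-derived PLACEHOLDER, mouse symbols).
Cpt1a
Cpt2
Acadm
Acadl
Acadvl
Hadha
Hadhb
Echs1
Acox1
Acsl1
Acsl4
Fasn
Acaca
Scd1
Elovl6
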