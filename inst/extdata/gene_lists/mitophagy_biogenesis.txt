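# Mitophagy / mitochondrial-biogenesis module (PLACEHOLDER, mouse symbols).
Pink1
Prkn
Sqstm1
Map1lc3b
Bnip3
Bnip3l
Fundc1
Optn
Ppargc1a
Ppargc1b
Nrf1
Tfam
Tfb2m
Polg
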