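# Vascular / endothelial marker module (PLACEHOLDER, mouse symbols).
Pecam1
Cdh5
Cldn5
Tek
Tie1
Eng
Emcn
Esam
Vwf
Flt1
Kdr
Sox17
Sox18
Erg
Egfl7
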