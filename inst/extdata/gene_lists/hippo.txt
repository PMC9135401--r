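# Hippo signalling module (KEGG-derived PLACEHOLDER, mouse symbols).
Yap1
Wwtr1
Tead1
Tead2
Lats1
Lats2
Stk3
Stk4
Sav1
Mob1a
Mob1b
Ctgf
Cyr61
Amotl2
Ajuba
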