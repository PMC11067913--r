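12	9	(Africa Arabia Australia Caribbean Eurasia India NorthAmerica SouthAmerica Sunda)
Dibamus_sp	100011001
Gekko_sp	011000011
Scincus_sp	100110100
Lacerta_sp	001001110
Teius_sp	111000001
Python_sp	100110100
Naja_sp	000101101
Anolis_sp	101001001
Iguana_sp	101001100
Anguis_sp	000110101
Shinisaurus_sp	010100011
Varanus_sp	101000001
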