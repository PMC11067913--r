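name	mrca_taxa	required_areas
toxicofera	Naja_sp,Anolis_sp	Eurasia
iguania_anguimorpha	Anolis_sp,Varanus_sp	Eurasia
paleoanguimorpha	Shinisaurus_sp,Varanus_sp	Eurasia
laterata	Lacerta_sp,Teius_sp	Eurasia
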