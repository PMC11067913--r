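(Dibamus_sp:193,(Gekko_sp:180,(Scincus_sp:170,((Lacerta_sp:100,Teius_sp:100):68,((Python_sp:90,Naja_sp:90):72,((Anolis_sp:120,Iguana_sp:120):35,(Anguis_sp:140,(Shinisaurus_sp:80,Varanus_sp:80):60):15):7):6):2):10):13);
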