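((Trifolium_repens:60,Lotus_corniculatus:60):40,((Cirsium_arvense:50,Daucus_carota:50):30,Campanula_rotundifolia:80):20):0;
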