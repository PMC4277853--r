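plant,Apis_mellifera,Bombus_terrestris,Episyrphus_balteatus,Pieris_rapae,Lasioglossum_calceatum
Trifolium_repens,12,8,2,0,3
Lotus_corniculatus,5,6,0,1,0
Cirsium_arvense,3,0,4,2,1
Daucus_carota,2,0,5,0,2
Campanula_rotundifolia,0,3,0,0,1
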