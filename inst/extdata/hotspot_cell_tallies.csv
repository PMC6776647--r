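site,whale_cells_photo,whale_cells_model,total_cells
Hawaiian Islands (USA),4,4,565
Baja California (Mexico),7,6,2974
Valdes Peninsula (Argentina),7,4,1295
Witsand (South Africa),40,35,3312
Memba (Mozambique),NA,1,594
Coral Sea (Australia),2,2,346
Enderby Island (New Zealand),8,4,790
Peruvian coast (Peru),0,0,1307
Canary Islands (Spain),0,0,1045
Japanese coast (Japan),0,0,1120
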