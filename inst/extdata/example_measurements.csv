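individual_id,species,level,branch_path,radius_um
cs01,C_suffusus,1,1,29.15
cs01,C_suffusus,2,2a,13.87
cs01,C_suffusus,2,2b,10.11
cs01,C_suffusus,2,2c,5.59
cs01,C_suffusus,3,3a1,6.35
cs01,C_suffusus,3,3a2,8.02
cs01,C_suffusus,3,3b1,5.40
cs01,C_suffusus,3,3b2,5.24
mf01,M_fulvipes,1,1,32.83
mf01,M_fulvipes,2,2a,17.67
mf01,M_fulvipes,2,2b,14.44
mf01,M_fulvipes,3,3a1,11.78
mf01,M_fulvipes,3,3a2,8.13
mf01,M_fulvipes,3,3b1,6.19
mf01,M_fulvipes,3,3b2,6.61
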