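name,formula,M_g_mol,T_b_C,T_c_C,p_c_Pa,rho_liquid_kg_m3,sigma_ref_N_m,sigma_ref_T_C,h_fg_b_J_kg
PFB,C4F10,238.03,-2,113.2,2323000,1594,0.0094,25,96200
OFP,C3F8,188.02,-36.7,71.9,2640000,1601,0.0115,-36.7,104200
PFP,C5F12,288.03,29.2,149.1,2045000,1620,0.0095,25,89900
PFH,C6F14,338.04,57.1,174.1,1868000,1680,0.0114,25,84000
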