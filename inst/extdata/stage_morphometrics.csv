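stage,L_sarcomere_um,W_I_band_um,W_H_zone_um,W_Z_disc_um,n_thick,spacing_nm
36h APF,1.80,0.16,0.92,0.24,23,53
48h APF,2.20,0.26,1.36,0.14,32,47
72h APF,3.00,0.43,0.438,0.098,134,47
24h AE,3.40,0.16,0.134,0.094,846,47
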