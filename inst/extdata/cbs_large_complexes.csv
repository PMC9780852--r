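system_id,method,minus_de
alpha-PHB,fit_adz_atz,23.56
beta-PHB,fit_adz_atz,10.18
GGG,fit_adz_atz,8.95
GCGC,fit_adz_atz,56.79
C2C2PD,fit_adz_atz,87.81
alpha-PHB,focal_atz_aqz,24.03
beta-PHB,focal_atz_aqz,10.23
GGG,focal_atz_aqz,8.87
GCGC,focal_atz_aqz,56.44
C2C2PD,focal_atz_aqz,86.19
alpha-PHB,sapt_dft,26.14
beta-PHB,sapt_dft,11.43
GGG,sapt_dft,6.88
GCGC,sapt_dft,54.69
C2C2PD,sapt_dft,82.68
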