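strain: WT
alpha_max: '0.20399999999999999'
K_alpha: '0.13'
R_cell_max: '180'
K_N: '4'
sens: '2'
R_cyt_max: '230'
k_mit_c3: '2.7999999999999998'
k_mit: '5.5'
R_vac_max: '1140'
K_vac: '11'
nvac: '3'
R_cia_max: '56'
K_cia: '3.7999999999999998'
ncia: '3'
R_isu_max: '180'
K_isu: '220'
nisu: '2.2999999999999998'
k_vp: '1.1000000000000001e-07'
nvp: '2.3999999999999999'
k_23: '5.2000000000000002'
FS_sp: '370'
n23: '1.6000000000000001'
k_mp: '0.089999999999999997'
k_O2: '25'
k_res: '9'
O2_cyt: '100'
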