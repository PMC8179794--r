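name,kd_il2ra_nM,kd_il2rbg_nM,fc_orientation
IL2_wt_Nterm,10,1.0,N-terminal
IL2_wt_Cterm,55,0.45,C-terminal
V91K_Nterm,11,6.5,N-terminal
N88D_Nterm,9,30,N-terminal
R38Q_Cterm,120,0.5,C-terminal
F42K_Cterm,420,0.6,C-terminal
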