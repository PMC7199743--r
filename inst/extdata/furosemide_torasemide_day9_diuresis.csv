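furosemide_dose_mgkg,furosemide_diuresis_mL,torasemide_dose_mgkg,torasemide_diuresis_mL
0,210,0,210
1,212,0.1,220
2,365,0.2,403
5,867,0.3,773
8,1063,0.4,1150
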