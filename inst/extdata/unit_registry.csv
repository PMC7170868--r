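unit,factor_to_ug_per_ml,needs_mw
ug/ml,1,FALSE
mcg/ml,1,FALSE
mg/l,1,FALSE
ng/ml,0.001,FALSE
ug/l,0.001,FALSE
pg/ml,1e-06,FALSE
ng/l,1e-06,FALSE
mg/ml,1000,FALSE
g/l,1000,FALSE
g/ml,1e+06,FALSE
mg/dl,10,FALSE
ug/dl,0.01,FALSE
g/dl,10000,FALSE
mg/m^3,0.001,FALSE
ug/m^3,1e-06,FALSE
ng/m^3,1e-09,FALSE
mol/l,1000,TRUE
mmol/l,1,TRUE
umol/l,0.001,TRUE
nmol/l,1e-06,TRUE
pmol/l,1e-09,TRUE
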