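# Exchange fluxes of the hRBC model (loads have two-sided
# stoichiometry, so auto-detection needs this explicit list)
EX_GLC
EX_LAC_i
EX_LAC_o
EX_PYR
EX_HX
EX_ADE
EX_ADO
EX_INO
EX_NH3
EX_CO2
EX_PI
EX_H
EX_H2O
ATPload
NADHload
NADPHload
DPGload
EX_ADP
EX_AMP
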