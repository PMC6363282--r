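# Allosterically regulated reactions of hRBC metabolism (literature set)
HK
PFK
DPGM
G6PDH
PDGH
PK
TKI
TKII
PRPPsyn
AdPRT
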