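# Currency (cofactor) exchange fluxes: pathways whose only
# boundary traffic is through these are type II futile cycles
ATPload
NADHload
NADPHload
EX_PI
EX_H
EX_H2O
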