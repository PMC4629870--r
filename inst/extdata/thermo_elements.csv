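# Element composition of thermodynamic species (acetate and methylamine as
# the ionic forms written in the bundled reactions: CH3COO-, CH3NH2).
species,C,H,O,S,N
h2,0,2,0,0,0
co2,1,0,2,0,0
ch4,1,4,0,0,0
acetate,2,3,2,0,0
sulphate,0,0,4,1,0
hs,0,1,0,1,0
h2o,0,2,1,0,0
h_plus,0,1,0,0,0
nh4,0,4,0,0,1
methylamine,1,5,0,0,1
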