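# Bundled catabolic reaction energetics (editable defaults).
# dg0: Gibbs energy of reaction at 298.15 K, kJ per mol reaction advance,
#      pH-7 convention (H+ activity referenced to 1e-7 mol/L).
# dh0: reaction enthalpy, kJ per mol, assumed temperature-independent.
# Values compiled from standard anaerobe-energetics tables.
reaction,dg0,dh0
hydrogenotrophic_methanogenesis,-131.0,-253.0
hydrogenotrophic_acetogenesis,-94.9,-270.0
hydrogenotrophic_sulphate_reduction,-151.9,-250.0
acetoclastic_methanogenesis,-35.8,-15.0
acetoclastic_sulphate_reduction,-47.6,-58.0
methylotrophic_methanogenesis,-225.0,-290.0
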