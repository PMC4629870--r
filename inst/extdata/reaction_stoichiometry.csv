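# Signed stoichiometric coefficients (substrates negative) per reaction.
# Gas-phase species: h2, co2, ch4 (activities in bar); h2o activity 1;
# h_plus activity 10^-(pH-7) under the pH-7 reference convention.
reaction,species,coefficient
hydrogenotrophic_methanogenesis,h2,-4
hydrogenotrophic_methanogenesis,co2,-1
hydrogenotrophic_methanogenesis,ch4,1
hydrogenotrophic_methanogenesis,h2o,2
hydrogenotrophic_acetogenesis,h2,-4
hydrogenotrophic_acetogenesis,co2,-2
hydrogenotrophic_acetogenesis,acetate,1
hydrogenotrophic_acetogenesis,h_plus,1
hydrogenotrophic_acetogenesis,h2o,2
hydrogenotrophic_sulphate_reduction,h2,-4
hydrogenotrophic_sulphate_reduction,sulphate,-1
hydrogenotrophic_sulphate_reduction,h_plus,-1
hydrogenotrophic_sulphate_reduction,hs,1
hydrogenotrophic_sulphate_reduction,h2o,4
acetoclastic_methanogenesis,acetate,-1
acetoclastic_methanogenesis,h_plus,-1
acetoclastic_methanogenesis,ch4,1
acetoclastic_methanogenesis,co2,1
acetoclastic_sulphate_reduction,acetate,-1
acetoclastic_sulphate_reduction,sulphate,-1
acetoclastic_sulphate_reduction,h_plus,-2
acetoclastic_sulphate_reduction,co2,2
acetoclastic_sulphate_reduction,hs,1
acetoclastic_sulphate_reduction,h2o,2
methylotrophic_methanogenesis,methylamine,-4
methylotrophic_methanogenesis,h_plus,-4
methylotrophic_methanogenesis,h2o,-2
methylotrophic_methanogenesis,ch4,3
methylotrophic_methanogenesis,co2,1
methylotrophic_methanogenesis,nh4,4
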