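# Henry solubility constants at 298.15 K (mol L-1 bar-1) and van't Hoff
# temperature coefficients C (K): K(T) = k298 * exp(C * (1/T - 1/298.15)).
species,k298,vant_hoff_c
h2,7.8e-4,500
ch4,1.4e-3,1700
co2,3.4e-2,2400
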