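variable,percent_contribution,permutation_importance
bio6,20.8,0.7
altitude,16.8,32.2
bio8,14.7,19
slope,14.6,4.3
alum_sat,12.2,0.7
bio12,5,1.9
bio4,3.5,7.9
bio17,3.2,5.5
bio18,2.7,3.8
ph_water,2.2,11.5
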