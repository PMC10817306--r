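model,lag,estimate,se
ar1_2pl,1,0.572,0.107
ar2_2pl,1,0.667,0.116
ar2_2pl,2,0.370,0.121
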