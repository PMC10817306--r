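model,item,slope,slope_se,threshold,threshold_se
2pl,1,0.855,0.146,-1.322,0.129
2pl,2,1.997,0.324,-3.554,0.375
2pl,3,1.692,0.232,-2.068,0.208
2pl,4,4.089,0.730,-4.106,0.647
2pl,5,4.933,1.018,-5.489,1.010
2pl,6,2.375,0.317,-2.129,0.253
2pl,7,1.550,0.198,-1.230,0.155
2pl,8,1.612,0.199,-0.502,0.136
2pl,9,1.264,0.163,-0.402,0.120
2pl,10,2.196,0.286,0.703,0.166
2pl,11,1.513,0.186,0.816,0.137
2pl,12,1.136,0.157,0.910,0.125
ar1_2pl,1,0.856,0.150,-1.322,0.129
ar1_2pl,2,1.816,0.318,-3.051,0.375
ar1_2pl,3,1.502,0.228,-1.464,0.228
ar1_2pl,4,3.950,0.833,-3.631,0.731
ar1_2pl,5,4.187,0.936,-4.490,0.938
ar1_2pl,6,2.019,0.311,-1.465,0.264
ar1_2pl,7,1.243,0.197,-0.715,0.172
ar1_2pl,8,1.379,0.199,-0.063,0.153
ar1_2pl,9,0.971,0.165,-0.043,0.131
ar1_2pl,10,2.016,0.307,1.045,0.177
ar1_2pl,11,1.173,0.192,1.013,0.133
ar1_2pl,12,0.911,0.159,1.097,0.126
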