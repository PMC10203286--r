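condition,start_min,tte_min_mean,tte_min_sd,mid_min_mean,mid_min_sd,end_min_mean,end_min_sd,rpe_mean,rpe_sd
90,0.5,15.25,2.50,7.39,1.37,14.57,2.61,18.8,0.9
100,0.5,5.68,1.10,2.68,0.54,5.18,1.10,19.1,0.9
110,0.5,2.65,0.78,1.28,0.40,2.33,0.78,19.1,0.6
120,0.5,1.58,0.49,0.73,0.25,1.26,0.56,18.9,1.0
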