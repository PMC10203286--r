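condition,window,impact_peaks,pct_steps,n_runners,pct_runners
90,start,17,7,4,31
90,mid,54,21,9,69
90,end,129,50,12,92
100,start,34,13,5,38
100,mid,92,35,12,92
100,end,133,51,11,85
110,start,60,23,10,77
110,mid,101,39,10,77
110,end,158,61,13,100
120,start,90,35,10,77
120,mid,106,41,13,100
120,end,127,49,12,92
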