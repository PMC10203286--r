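variable,mean,sd
n_runners,13,0
age_y,25.7,4.4
height_cm,179,5
mass_kg,68,5
vo2max_ml_min_kg,64.2,4.2
ps_m_s,5.3,0.3
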