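variable,count_low,count_mid,count_high,pct_low,pct_mid,pct_high,missing_pct
total,4134,18365,3347,16.0,71.1,12.9,1.1
outcome,1619,4588,591,39.2,25.0,17.7,0
smoker,589,2734,250,14.2,14.9,7.5,0
diabetes,939,3830,523,22.7,20.9,15.6,0.2
atrial_fib,1388,4820,770,33.6,26.2,23.0,0.5
prev_stroke,814,3404,510,19.7,18.5,15.2,0.2
antihypertensives,3027,12059,1930,73.2,65.9,57.7,0.3
statins,1201,5849,979,29.1,31.8,29.3,0.3
antiplatelets,1587,6187,929,38.4,33.7,27.8,0.2
anticoagulants,504,2142,355,12.2,11.7,10.6,0.2
severe,785,3111,542,35.2,28.7,24.7,41.8
reperfusion,464,2697,586,11.2,14.7,17.5,0.0
stroke_unit,3770,16934,3107,91.2,92.2,92.8,1.1
female,2483,7869,1209,60.1,42.8,36.1,0
age_mean,80.5,73.9,70.3,,,,0
age_sd,10.7,11.6,12.5,,,,0
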