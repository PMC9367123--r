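parameter,scale,on_oxygen,lower,upper,points
resp_rate,both,any,-Inf,8,3
resp_rate,both,any,9,11,1
resp_rate,both,any,12,20,0
resp_rate,both,any,21,24,2
resp_rate,both,any,25,Inf,3
heart_rate,both,any,-Inf,40,3
heart_rate,both,any,41,50,1
heart_rate,both,any,51,90,0
heart_rate,both,any,91,110,1
heart_rate,both,any,111,130,2
heart_rate,both,any,131,Inf,3
sbp,both,any,-Inf,90,3
sbp,both,any,91,100,2
sbp,both,any,101,110,1
sbp,both,any,111,219,0
sbp,both,any,220,Inf,3
temperature,both,any,-Inf,35.0,3
temperature,both,any,35.1,36.0,1
temperature,both,any,36.1,38.0,0
temperature,both,any,38.1,39.0,1
temperature,both,any,39.1,Inf,2
spo2,1,any,-Inf,91,3
spo2,1,any,92,93,2
spo2,1,any,94,95,1
spo2,1,any,96,Inf,0
spo2,2,any,-Inf,83,3
spo2,2,any,84,85,2
spo2,2,any,86,87,1
spo2,2,any,88,92,0
spo2,2,air,93,Inf,0
spo2,2,oxygen,93,94,1
spo2,2,oxygen,95,96,2
spo2,2,oxygen,97,Inf,3
supplemental_o2,both,air,-Inf,Inf,0
supplemental_o2,both,oxygen,-Inf,Inf,2
consciousness,both,any,0,0,0
consciousness,both,any,1,4,3
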