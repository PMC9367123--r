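mode,upper,level,label
flow,2,1,Low
flow,5,2,Low-moderate
flow,9,3,Moderate
flow,15,4,High
flow,Inf,5,Very high
concentration,28,1,Low
concentration,40,2,Low-moderate
concentration,60,3,Moderate
concentration,80,4,High
concentration,Inf,5,Very high
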