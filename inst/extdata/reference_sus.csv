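cohort,mean,sd,n
A1,75.0,18.9,9
A2,75.0,16.8,10
A3,63.3,16.2,9
B1,76.2,11.7,26
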