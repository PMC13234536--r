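cohort,trial,mean,sd,n
A1,1,15.0,0.0,9
A1,2,15.0,0.0,9
A1,3,15.0,0.0,9
A2,1,8.9,1.5,10
A2,2,8.9,1.3,10
A2,3,9.6,1.8,10
A3,1,5.6,1.9,9
A3,2,5.3,0.7,9
A3,3,5.5,1.5,9
B1,1,15.0,0.1,26
B1,2,7.5,1.8,26
B1,3,5.0,1.5,26
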