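band,mean,sd,n
under65,0.85,0.06,500
65plus,0.77,0.02,500
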