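source,lambda,uncertainty
this_work,1.108,0.001
granero,1.1087,0.0011
selvam_bhola,1.097,NA
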