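sex,age_lo,age_hi,weight
male,18,120,1.0
female,18,120,0.8
male,10,17,0.75
female,10,17,0.75
male,5,9,0.6
female,5,9,0.6
male,1,4,0.4
female,1,4,0.4
male,0,0,0.25
female,0,0,0.25
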