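individual	population
p1_01	pop1
p1_02	pop1
p1_03	pop1
p1_04	pop1
p2_01	pop2
p2_02	pop2
p2_03	pop2
p2_04	pop2
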