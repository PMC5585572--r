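# spikegibbs potential file
h=-0.80000000000000004 : w0(0)
h=-0.59999999999999998 : w1(0)
h=0.5 : w0(0) w1(0)
h=0.40000000000000002 : w0(0) w0(1)
h=0.29999999999999999 : w0(0) w1(1)
h=-0.20000000000000001 : w1(0) w0(1)
h=0.10000000000000001 : w1(0) w1(1)
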