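trait	module
t1	M1
t2	M1
t3	M2
t4	M2
t5	M3
t6	M3
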