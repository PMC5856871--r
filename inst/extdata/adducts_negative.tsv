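name	charge	multimer	mass_shift
[M-H]-	-1	1	-1.00727647
[M+Cl]-	-1	1	34.96940126
[M+HCOO]-	-1	1	44.99820286
[2M-H]-	-1	2	-1.00727647
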