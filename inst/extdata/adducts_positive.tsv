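name	charge	multimer	mass_shift
[M+H]+	1	1	1.00727647
[M+Na]+	1	1	22.98922070
[M+K]+	1	1	38.96315791
[M+NH4]+	1	1	18.03382555
[2M+H]+	1	2	1.00727647
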