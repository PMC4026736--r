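imputed	0	1	2
0	553	0	0
1	1	45	0
2	1	5	25
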