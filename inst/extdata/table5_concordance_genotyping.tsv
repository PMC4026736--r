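imputed	*1/*1	*1/*3A	*1/*3C
*1/*1	553	0	0
*1/*3A	0	26	0
*1/*3C	1	0	3
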