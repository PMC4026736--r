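imputed	*1/*1	*1/*3A	*1/*3C	*3A/*3A	*3A/*3C	*3C/*3C
*1/*1	0	0	0	0	0	0
*1/*3A	0	19	0	0	0	0
*1/*3C	0	0	9	0	0	0
*3A/*3A	1	0	0	6	0	0
*3A/*3C	0	0	1	0	3	1
*3C/*3C	0	0	4	1	1	13
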