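genotype	Caucasian	African	Hispanic	Asian
*1/*1	58981	14761	5275	1606
*1/*3A	4119	286	322	19
*1/*3B	10	1	1	0
*1/*3C	697	1416	147	71
*3A/*3A	81	1	5	0
*3A/*3B	1	0	0	0
*3A/*3C	23	15	2	0
*3B/*3C	75	0	11	0
*3C/*3C	11	39	1	2
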