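allele	Caucasian	African	Hispanic	Asian	Total
*1	122787	31225	11020	3302	168333
*3A	4305	303	334	19	4961
*3B	86	1	12	0	99
*3C	817	1509	162	75	2563
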