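tissue	up	down	total
brain	91	45	13528
eye	112	84	14459
ovary	1562	240	10836
testis	731	249	11887
liver	378	648	7385
intestine	2279	492	9905
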