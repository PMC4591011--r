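gene_symbol	gene_name	gene_id	rpkm_gc	rpkm_sf	sr_printed
1-sf	L-SF precursor	010134	7.23	2.22	-1.70
ZP2(1 of 3)	Zona pellucida glycoprotein 2	006621	457.84	355.68	-0.36
ZP2(2 of 3)	Si: dkeyp-50f7.2	012471	2068.80	2059.62	-0.01
ZP2(3 of 3)	Si: ch211-223m11.2	012527	1223.85	1321.62	0.11
zp3b	Zona pellucida glycoprotein 3b	016064	678.32	710.87	0.07
chgHm	Choriogenin H minor	010086	1.61	0.65	-1.31
chgH	Choriogenin H precursor	010880	7.42	2.61	-1.51
zpB	ZPB domain-containing protein	016580	1824.70	1722.53	-0.08
zpC3	ZPC domain containing protein 3	009867	907.89	876.16	-0.05
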