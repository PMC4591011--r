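gene_symbol	gene_id	sr_intestine	sr_brain	sr_eye	sr_ovary	sr_testis	sr_liver	z_printed
prdx1	010533	4.66	-0.15	0.07	-0.42	-0.36	0.53	4.72
GSTO1	006201	3.43	-0.27	-0.05	-0.32	-0.64	-0.07	3.52
cyba	009360	3.45	-0.60	-0.46	-1.29	0.11	-0.48	3.79
steap3	004437	3.43	-0.20	0.11	-0.06	-0.20	0.17	3.45
pgd	005212	3.02	-0.19	-0.16	0.45	0.28	0.21	3.08
arf2	014113	2.79	-0.13	0.03	0.42	0.17	0.02	2.83
txndc2	007575	2.52	0.08	0.17	0.08	-0.27	-0.16	2.55
scdb	006839	-2.76	-0.26	-0.17	1.01	0.80	0.47	3.10
hsd11b1l	004562	-2.88	-0.02	-0.39	-0.77	0.31	-0.69	3.10
cdo1	003390	-5.83	0.14	0.72	-2.12	-0.21	-0.67	6.28
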