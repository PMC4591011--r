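gene_symbol	gene_id	sr_brain	sr_eye	sr_ovary	sr_testis	sr_liver	sr_intestine	z_printed
dusp1	006559	1.31	1.12	1.18	0.40	1.02	0.81	2.49
hif1a1	002004	0.31	0.28	1.25	1.42	1.49	1.30	2.76
hsp70.3	000233	2.06	2.14	-0.16	-0.34	2.57	1.47	4.21
keap1a	013993	-0.13	-0.41	-1.51	-1.52	-1.00	-1.11	2.64
klf9	010690	2.69	2.72	0.59	0.40	4.48	4.34	7.35
klf13	007542	2.06	1.25	0.35	1.35	1.88	2.56	4.22
mat2ab	006298	0.23	0.10	1.44	1.26	2.36	1.22	3.28
nrld4b	015399	-0.02	1.29	1.38	1.68	0.34	1.16	2.80
odc1	017758	-0.43	-0.23	2.04	1.04	2.44	3.07	4.57
tmem39a	003717	0.21	-0.11	1.34	1.14	1.98	1.05	2.86
usp10	007919	-0.36	-0.24	1.19	1.07	1.46	1.06	2.45
zfp36	008378	1.76	1.55	1.28	0.31	-0.27	1.84	3.27
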