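gene	direction	log2_ratio	ci_lo	ci_hi
Kcnj15	down	-5.51	-9.57	-2.48
Ano2	down	-2.59	-5.5	0
Kcnb1	down	-2.44	-1.85	-1
Kcnv2	down	-2.4	-4.85	0
Kcnip1	down	-2.36	-3.88	-0.88
Kcnmb1	down	-1.98	-3.28	0.69
Kcns1	down	-1.88	-6.84	-0.42
Kcnj8	down	-1.79	-4.71	2.17
Kcnd3	down	-1.78	-2.63	0.29
Nalcn	down	-1.77	-3.43	-0.85
Clca2	down	-1.76	-6.72	0.65
Kcne3	down	-1.67	-1.84	-0.15
Asic1	down	-1.64	-6.44	0
Clcn4	down	-1.61	-2.61	-0.95
Trpm8	down	-1.61	-2.09	-0.99
Kcnc1	up	4.32	0.68	5.93
Kcnc3	up	3.46	0.76	5.94
Trpc3	up	3.06	3.73	6.5
Catsper3	up	2.83	0.14	5.75
Kcng3	up	2.81	2.77	6.65
Tmc7	up	2.77	1.99	5.53
Gjc3	up	2.75	0.03	4.35
Scnn1g	up	2.56	2.77	5.45
Asic2	up	2.52	0.66	4.65
Kcnmb3	up	2.34	0	4.73
Cracr2a	up	2.32	0.01	1.96
Kcnn3	up	2.07	0.57	4.09
Tmc4	up	1.94	0.27	2.47
Asic4	up	1.75	0.52	2.76
Kcnj11	up	1.74	0	6.56
Trpv6	up	1.7	0.01	5.43
Hvcn1	up	1.69	0.98	2.84
Trpv1	up	1.61	0.98	2.07
Kcnk7	up	1.6	-1.85	1.03
Cacna1d	up	1.57	0.32	2.09
Asic5	up	1.55	0	5.78
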