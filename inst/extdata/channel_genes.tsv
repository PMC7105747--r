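symbol	family
Kcna1	Kv
Kcna2	Kv
Kcna3	Kv
Kcna4	Kv
Kcna5	Kv
Kcna6	Kv
Kcna7	Kv
Kcna10	Kv
Kcnb1	Kv
Kcnb2	Kv
Kcnc1	Kv
Kcnc2	Kv
Kcnc3	Kv
Kcnc4	Kv
Kcnd1	Kv
Kcnd2	Kv
Kcnd3	Kv
Kcnf1	Kv
Kcng1	Kv
Kcng2	Kv
Kcng3	Kv
Kcng4	Kv
Kcnh1	Kv
Kcnh2	Kv
Kcnh3	Kv
Kcnh4	Kv
Kcnh5	Kv
Kcnh6	Kv
Kcnh7	Kv
Kcnh8	Kv
Kcnq1	Kv
Kcnq2	Kv
Kcnq3	Kv
Kcnq4	Kv
Kcnq5	Kv
Kcns1	Kv
Kcns2	Kv
Kcns3	Kv
Kcnv1	Kv
Kcnv2	Kv
Kcnab1	Kv-beta
Kcnab2	Kv-beta
Kcnab3	Kv-beta
Kcne1	Kv-aux
Kcne2	Kv-aux
Kcne3	Kv-aux
Kcne4	Kv-aux
Kcne5	Kv-aux
Kcnip1	Kv-aux
Kcnip2	Kv-aux
Kcnip3	Kv-aux
Kcnip4	Kv-aux
Kcnma1	KCa
Kcnmb1	KCa-beta
Kcnmb2	KCa-beta
Kcnmb3	KCa-beta
Kcnmb4	KCa-beta
Kcnn1	KCa
Kcnn2	KCa
Kcnn3	KCa
Kcnn4	KCa
Kcnt1	KNa
Kcnt2	KNa
Kcnu1	KCa
Kcnj1	Kir
Kcnj2	Kir
Kcnj3	Kir
Kcnj4	Kir
Kcnj5	Kir
Kcnj6	Kir
Kcnj8	Kir
Kcnj9	Kir
Kcnj10	Kir
Kcnj11	Kir
Kcnj12	Kir
Kcnj13	Kir
Kcnj14	Kir
Kcnj15	Kir
Kcnj16	Kir
Kcnk1	K2P
Kcnk2	K2P
Kcnk3	K2P
Kcnk4	K2P
Kcnk5	K2P
Kcnk6	K2P
Kcnk7	K2P
Kcnk9	K2P
Kcnk10	K2P
Kcnk12	K2P
Kcnk13	K2P
Kcnk15	K2P
Kcnk16	K2P
Kcnk18	K2P
Hcn1	HCN
Hcn2	HCN
Hcn3	HCN
Hcn4	HCN
Scn1a	Nav
Scn2a	Nav
Scn3a	Nav
Scn4a	Nav
Scn5a	Nav
Scn7a	Nav
Scn8a	Nav
Scn9a	Nav
Scn10a	Nav
Scn11a	Nav
Scn1b	Nav-beta
Scn2b	Nav-beta
Scn3b	Nav-beta
Scn4b	Nav-beta
Nalcn	Na-leak
Cacna1a	Cav
Cacna1b	Cav
Cacna1c	Cav
Cacna1d	Cav
Cacna1e	Cav
Cacna1f	Cav
Cacna1g	Cav
Cacna1h	Cav
Cacna1i	Cav
Cacna1s	Cav
Cacna2d1	Cav-aux
Cacna2d2	Cav-aux
Cacna2d3	Cav-aux
Cacna2d4	Cav-aux
Cacnb1	Cav-beta
Cacnb2	Cav-beta
Cacnb3	Cav-beta
Cacnb4	Cav-beta
Cacng1	Cav-gamma
Cacng2	Cav-gamma
Cacng3	Cav-gamma
Cacng4	Cav-gamma
Cacng5	Cav-gamma
Cacng6	Cav-gamma
Cacng7	Cav-gamma
Cacng8	Cav-gamma
Trpa1	TRP
Trpc1	TRP
Trpc2	TRP
Trpc3	TRP
Trpc4	TRP
Trpc5	TRP
Trpc6	TRP
Trpc7	TRP
Trpm1	TRP
Trpm2	TRP
Trpm3	TRP
Trpm4	TRP
Trpm5	TRP
Trpm6	TRP
Trpm7	TRP
Trpm8	TRP
Trpv1	TRP
Trpv2	TRP
Trpv3	TRP
Trpv4	TRP
Trpv5	TRP
Trpv6	TRP
Mcoln1	TRP
Mcoln2	TRP
Mcoln3	TRP
Pkd2	TRP
Pkd2l1	TRP
Pkd2l2	TRP
Asic1	ASIC
Asic2	ASIC
Asic3	ASIC
Asic4	ASIC
Asic5	ASIC
Scnn1a	ENaC
Scnn1b	ENaC
Scnn1g	ENaC
Clcn1	ClC
Clcn2	ClC
Clcn3	ClC
Clcn4	ClC
Clcn5	ClC
Clcn6	ClC
Clcn7	ClC
Clcnka	ClC
Clcnkb	ClC
Clca1	CLCA
Clca2	CLCA
Clca4	CLCA
Ano1	Anoctamin
Ano2	Anoctamin
Ano3	Anoctamin
Ano4	Anoctamin
Ano5	Anoctamin
Ano6	Anoctamin
Ano7	Anoctamin
Ano8	Anoctamin
Ano9	Anoctamin
Ano10	Anoctamin
Best1	Bestrophin
Best2	Bestrophin
Best3	Bestrophin
Cftr	ABC-Cl
P2rx1	P2X
P2rx2	P2X
P2rx3	P2X
P2rx4	P2X
P2rx5	P2X
P2rx6	P2X
P2rx7	P2X
Orai1	CRAC
Orai2	CRAC
Orai3	CRAC
Cracr2a	CRAC-reg
Cracr2b	CRAC-reg
Hvcn1	Hv
Catsper1	CatSper
Catsper2	CatSper
Catsper3	CatSper
Catsper4	CatSper
Tmc1	TMC
Tmc2	TMC
Tmc3	TMC
Tmc4	TMC
Tmc5	TMC
Tmc6	TMC
Tmc7	TMC
Tmc8	TMC
Piezo1	Piezo
Piezo2	Piezo
Gja1	Connexin
Gja3	Connexin
Gja4	Connexin
Gja5	Connexin
Gja6	Connexin
Gja8	Connexin
Gjb1	Connexin
Gjb2	Connexin
Gjb3	Connexin
Gjb4	Connexin
Gjb5	Connexin
Gjb6	Connexin
Gjc1	Connexin
Gjc2	Connexin
Gjc3	Connexin
Gjd2	Connexin
Gjd3	Connexin
Gjd4	Connexin
Gje1	Connexin
Panx1	Pannexin
Panx2	Pannexin
Panx3	Pannexin
Vdac1	Porin
Vdac2	Porin
Vdac3	Porin
Aqp1	Aquaporin
Aqp2	Aquaporin
Aqp3	Aquaporin
Aqp4	Aquaporin
Aqp5	Aquaporin
Aqp6	Aquaporin
Aqp7	Aquaporin
Aqp8	Aquaporin
Aqp9	Aquaporin
Aqp11	Aquaporin
Itpr1	IP3R
Itpr2	IP3R
Itpr3	IP3R
Ryr1	RyR
Ryr2	RyR
Ryr3	RyR
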