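level	group	clade	n_genera	n_genera_sampled	n_species	n_species_sampled
clade	Sciuroidea	Sciuroidea	61	58	307	200
family	Aplodontidae	Sciuroidea	1	1	1	1
family	Gliridae	Sciuroidea	9	7	28	15
family	Sciuridae	Sciuroidea	51	50	278	184
clade	Castorimorpha	Castorimorpha	14	14	102	90
family	Castoridae	Castorimorpha	2	2	2	2
family	Geomyidae	Castorimorpha	6	6	40	33
family	Heteromyidae	Castorimorpha	6	6	60	55
clade	Ctenohystrica	Ctenohystrica	72	59	275	158
family	Abrocomidae	Ctenohystrica	2	1	10	2
family	Bathyergidae	Ctenohystrica	5	5	15	14
family	Capromyidae	Ctenohystrica	6	1	8	1
family	Caviidae	Ctenohystrica	6	6	18	13
family	Chinchillidae	Ctenohystrica	3	3	7	6
family	Ctenodactylidae	Ctenohystrica	4	2	5	3
family	Ctenomyidae	Ctenohystrica	1	1	60	38
family	Cuniculidae	Ctenohystrica	1	1	2	2
family	Dasyproctidae	Ctenohystrica	2	2	13	5
family	Diatomyidae	Ctenohystrica	1	1	1	1
family	Dinomyidae	Ctenohystrica	1	1	1	1
family	Echimyidae	Ctenohystrica	21	17	86	44
family	Erethizontidae	Ctenohystrica	5	4	17	7
family	Hystricidae	Ctenohystrica	3	3	11	7
family	Myocastoridae	Ctenohystrica	1	1	1	1
family	Octodontidae	Ctenohystrica	8	8	13	11
family	Petromuridae	Ctenohystrica	1	1	1	1
family	Thryonomyidae	Ctenohystrica	1	1	2	1
clade	Anomaluromorpha	Anomaluromorpha	4	3	9	4
family	Pedetidae	Anomaluromorpha	1	1	2	1
family	Anomaluridae	Anomaluromorpha	3	2	7	2
clade	Myomorpha	Myomorpha	324	253	1568	813
family	Dipodidae	Myomorpha	16	7	51	10
family	Platacanthomyidae	Myomorpha	2	1	2	1
family	Arvicolinae	Myomorpha	28	25	151	111
family	Calomyscidae	Myomorpha	1	1	8	2
family	Cricetinae	Myomorpha	7	6	18	14
family	Deomyinae	Myomorpha	4	4	42	33
family	Gerbillinae	Myomorpha	16	14	103	40
family	Leimacomyinae	Myomorpha	1	0	1	0
family	Lophiomyinae	Myomorpha	1	1	1	1
family	Murinae	Myomorpha	124	88	560	231
family	Neotominae	Myomorpha	16	16	124	103
family	Nesomyidae	Myomorpha	21	17	61	28
family	Otomyinae	Myomorpha	3	3	23	16
family	Sigmodontinae	Myomorpha	74	61	377	231
family	Spalacidae	Myomorpha	6	6	36	9
family	Tylomyidae	Myomorpha	4	3	10	3
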