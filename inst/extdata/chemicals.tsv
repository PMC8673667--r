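chemical_id	name	synonym
1	1,3-Butadiene	1,3-butadiene
1	1,3-Butadiene	butadiene
2	4-Aminobiphenyl	4-aminobiphenyl
2	4-Aminobiphenyl	aminobiphenyl
3	5-Azacytidine	5-azacytidine
3	5-Azacytidine	azacytidine
3	5-Azacytidine	azacitidine
4	Arsenic	arsenic
4	Arsenic	arsenite
4	Arsenic	arsenate
5	Asbestos	asbestos
5	Asbestos	chrysotile
6	Benzo-a-pyrene	benzo-a-pyrene
6	Benzo-a-pyrene	benzo[a]pyrene
6	Benzo-a-pyrene	benzopyrene
7	Bisphenol A	bisphenol a
7	Bisphenol A	bisphenol-a
8	Cadmium	cadmium
8	Cadmium	cadmium chloride
9	Chloroform	chloroform
10	Cyclosporine	cyclosporine
10	Cyclosporine	cyclosporin
10	Cyclosporine	cyclosporin a
11	Dichloroacetate	dichloroacetate
11	Dichloroacetate	dichloroacetic acid
12	Diethylnitrosamine	diethylnitrosamine
12	Diethylnitrosamine	nitrosodiethylamine
13	Diethylstilbestrol	diethylstilbestrol
13	Diethylstilbestrol	stilbestrol
14	Ethene Oxide	ethene oxide
14	Ethene Oxide	ethylene oxide
15	Formaldehyde	formaldehyde
15	Formaldehyde	formalin
16	Fumonisin_B1	fumonisin b1
16	Fumonisin_B1	fumonisin
17	Genistein	genistein
18	Irinotecan	irinotecan
18	Irinotecan	cpt-11
19	Methylene Chloride	methylene chloride
19	Methylene Chloride	dichloromethane
20	Nafenopin	nafenopin
21	Okadaic Acid	okadaic acid
22	Phenobarbital	phenobarbital
22	Phenobarbital	phenobarbitone
23	Pyridine	pyridine
24	Styrene	styrene
25	Sulindac	sulindac
25	Sulindac	sulindac sulfide
25	Sulindac	sulindac sulfone
26	TCDD	tcdd
26	TCDD	tetrachlorodibenzo-p-dioxin
27	Thiobenzamide	thiobenzamide
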