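name	role	exemplar	counter
isopropyl	clear_positive	CC(C)c1ccccc1	CC(C)(C)c1ccccc1
amino	clear_positive	NCCc1ccccc1	CC(N)=O
carboxylic acid ethyl ester	clear_positive	CCOC(=O)c1ccccc1	COC(=O)c1ccccc1
indole	clear_positive	c1ccc2[nH]ccc2c1	c1ccc2[nH]cnc2c1
3,4,5-trimethoxyphenyl	clear_positive	COc1cc(CN)cc(OC)c1OC	COc1cc(CN)cc(OC)c1
morpholine	clear_positive	CN1CCOCC1	O1CCNCCC1
thieno[2,3-b]pyrimidine	clear_positive	c1ncnc2sccc12	c1ccc2c(c1)cncn2
sulfone	clear_positive	CS(=O)(=O)c1ccccc1	NS(=O)(=O)c1ccccc1
1,2,4-oxadiazole	secondary_positive	Cc1noc(C)n1	Cc1nnc(C)o1
1,3,4-thiadiazole	secondary_positive	Cc1nnc(C)s1	Cc1nccs1
piperazine	secondary_positive	CN1CCN(C)CC1	CN1CCCCC1
homo-piperazine	secondary_positive	C1CNCCNC1	C1CNCCN1
piperidine	secondary_positive	CN1CCCCC1	CN1CCNCC1
pyrimidine	potential_positive	c1ccncn1	c1ccncc1
pyrrole	potential_positive	Cn1cccc1	c1ccncc1
pyridine	potential_positive	c1ccncc1	c1ccncn1
thiophene	potential_positive	c1ccsc1	c1ccoc1
imidazolidine	potential_positive	CN1CCNC1	Cn1ccnc1
homo-piperidine	potential_positive	C1CCCNCC1	C1CCNCC1
pyrrolidine	potential_positive	CN1CCCC1	Cn1cccc1
homo-morpholine	potential_positive	C1CCOCCN1	C1COCCN1
oxazolidine	potential_positive	CN1CCOC1	Cc1occn1
isoxazole	potential_positive	Cc1cc(C)on1	Cc1ncco1
oxazole	potential_positive	Cc1ncco1	Cc1cc(C)on1
imidazole	potential_positive	Cn1ccnc1	Cn1nccc1
furan	potential_positive	c1ccoc1	c1ccsc1
thiazole	potential_positive	Cc1nccs1	Cc1nnc(C)s1
pyrazole	potential_positive	Cn1nccc1	Cn1ccnc1
tert-butyl	clear_negative	CC(C)(C)c1ccccc1	CC(C)c1ccccc1
vinyl	clear_negative	C=Cc1ccccc1	CC=Cc1ccccc1
cyclopropyl	clear_negative	C1CC1c1ccccc1	C1CCCC2CC12
cyclohexyl	clear_negative	C1CCCCC1c1ccccc1	OC1CCC(N)CC1
anellated cyclopropyl	clear_negative	C1CCCC2CC12	C1CC1c1ccccc1
anellated cycloheptyl	clear_negative	C1CCCc2ccccc2C1	C1CCCCCC1
dimethylamino	clear_negative	CN(C)c1ccccc1	CNc1ccccc1
diethylamino	clear_negative	CCN(CC)c1ccccc1	CN(C)c1ccccc1
nitro	clear_negative	O=[N+]([O-])c1ccccc1	Nc1ccccc1
pyrrolidine	clear_negative	CN1CCCC1	CN1CCCCC1
methylene hydroxy	clear_negative	OCc1ccccc1	Oc1ccccc1
ethylene hydroxy	clear_negative	OCCc1ccccc1	OCc1ccccc1
oxolane	clear_negative	C1CCOC1	C1CCOCC1
carboxylic acid	clear_negative	OC(=O)c1ccccc1	COC(=O)c1ccccc1
carboxylic acid methyl ester	clear_negative	COC(=O)c1ccccc1	CCOC(=O)c1ccccc1
biphenyl	clear_negative	c1ccc(-c2ccccc2)cc1	c1ccc2ccccc2c1
stilbene	clear_negative	C(=Cc1ccccc1)c1ccccc1	c1ccccc1CCc1ccccc1
1,2,3-triazole	clear_negative	Cn1ccnn1	Cn1cncn1
1,2,4-triazole	clear_negative	Cn1cncn1	Cn1ccnn1
tetrazole	clear_negative	Cn1cnnn1	Cn1ccnn1
pyrido[2,3-d]pyrimidine	clear_negative	c1ccc2ncncc2n1	c1ccc2c(c1)cncn2
1,3-dihydroisobenzofuran	clear_negative	C1OCc2ccccc21	c1ccc2occc2c1
chalcone	clear_negative	O=C(C=Cc1ccccc1)c1ccccc1	O=C(CCc1ccccc1)c1ccccc1
hydroquinone	clear_negative	Oc1ccc(O)cc1	Oc1cccc(O)c1
2-methoxyphenyl	clear_negative	COc1ccccc1C	COc1ccccc1
3-methoxyphenyl	clear_negative	COc1cccc(C)c1	COc1ccccc1C
2,5-dimethoxyphenyl	clear_negative	COc1ccc(OC)c(C)c1	COc1cc(C)cc(OC)c1
3,5-dimethoxyphenyl	clear_negative	COc1cc(C)cc(OC)c1	COc1ccc(OC)c(C)c1
unsubstituted thioamide	clear_negative	NC(=S)c1ccccc1	CNC(=S)c1ccccc1
oxazole	clear_negative	Cc1ncco1	Cc1cc(C)on1
urea	clear_negative	CNC(=O)Nc1ccccc1	CC(=O)Nc1ccccc1
thiourea	clear_negative	CNC(=S)Nc1ccccc1	CC(=S)Nc1ccccc1
4-anilinopyrimidine	basic_scaffold	c1ccc(Nc2ccncn2)cc1	CN(c1ccccc1)c1ccncn1
quinazoline	basic_scaffold	c1ccc2c(c1)cncn2	c1ccc2ncccc2c1
pyrrolo[3,2-d]pyrimidine	basic_scaffold	c1cc2ncncc2[nH]1	c1ccc2[nH]ccc2c1
pyrimido[5,4-b]indole	basic_scaffold	c1ccc2c(c1)[nH]c1ncncc21	c1ccc2c(c1)[nH]c1ccccc12
quinoline	basic_scaffold	c1ccc2ncccc2c1	c1ccc2c(c1)cncn2
thieno[2,3-b]pyrimidine	basic_scaffold	c1ncnc2sccc12	c1ccc2c(c1)cncn2
aniline	rejected_putative_positive	Nc1ccccc1	CNc1ccccc1
benzoyl	rejected_putative_positive	CC(=O)c1ccccc1	CC(=O)Cc1ccccc1
benzyl	rejected_putative_positive	NCc1ccccc1	Cc1ccccc1
cyano	rejected_putative_positive	N#Cc1ccccc1	NCc1ccccc1
9-deazapurine	rejected_putative_positive	c1cc2ncncc2[nH]1	c1ncc2[nH]cnc2n1
ether	rejected_putative_positive	CCOCC	COc1ccccc1
ethylenediamine	rejected_putative_positive	CNCCNC	CNCCCNC
methoxy	rejected_putative_positive	COc1ccccc1	CCOc1ccccc1
methoxyphenyl	rejected_putative_positive	COc1ccc(N)cc1	c1ccc2OCOc2c1
phenol	rejected_putative_positive	Oc1ccccc1	COc1ccccc1
phenyl	rejected_putative_positive	c1ccccc1	c1ccncc1
piperazine	rejected_putative_positive	CN1CCN(C)CC1	CN1CCCCC1
pyrimidine	rejected_putative_positive	c1ccncn1	c1ccncc1
pyridine	rejected_putative_positive	c1ccncc1	c1ccncn1
pyrrole	rejected_putative_positive	Cn1cccc1	c1ccncc1
resorcin	rejected_putative_positive	Oc1cccc(O)c1	Oc1ccc(O)cc1
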