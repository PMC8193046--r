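id,name,zinc_id,molport_id,smiles,abcb1_ic50_um,abcc1_ic50_um,abcg2_ic50_um,abcb1_active_10um,abcc1_active_10um,abcg2_active_10um
16,"2-((2-(3,4-dihydro-2H-benzo[b][1,4]dioxepin-7-yl)pyrrolidin-1-yl)methyl)-5-(5-methyl-3-phenyl-isoxazol-4-yl)-1,3,4-oxadiazole",08938070,005-547-575,CC1=C(C2=NN=C(O2)CN3CCCC3C4=CC5=C(OCCCO5)C=C4)C(C6=CC=CC=C6)=NO1,,,,TRUE,TRUE,TRUE
17,4-(1-(4-fluorophenyl)-1H-imidazole-5-carboxamido)cyclohexyl 1-(4-fluorophenyl)-1H-imidazole-5-carboxylate,09672163,004-504-763,FC1=CC=C(N2C=NC=C2C(NC3CCC(OC(C4=CN=CN4C5=CC=C(F)C=C5)=O)CC3)=O)C=C1,,,,TRUE,FALSE,TRUE
18,"3-(2-(4-(2-(azepan-1-yl)-2-oxoethyl)piperazin-1-yl)-2-oxoethyl)-5-(thiophen-2-yl)thieno[2,3-d]pyrimidin-4(3H)-one",14239968,005-770-351,O=C(N1CCN(CC1)CC(N2CCCCCC2)=O)CN3C=NC4=C(C3=O)C(C5=CC=CS5)=CS4,,,,FALSE,TRUE,TRUE
19,"(4-(benzo[d][1,3]dioxol-5-ylmethyl)piperazin-1-yl)(1-(5-(pyrrolidin-1-yl)-1,3,4-thiadiazol-2-yl)-1H-pyrrol-2-yl)methanone",15731308,007-821-780,O=C(C1=CC=CN1C2=NN=C(N3CCCC3)S2)N4CCN(CC4)CC5=CC=C6OCOC6=C5,,,,TRUE,FALSE,TRUE
20,"4-(3-(6-(pyridin-2-yl)-4,6,7a,12a-tetrahydro-1H-benzo[4,5]imidazo[1,2-a][1,3,5]triazino[1,2-c][1,3,5]triazin-2(3H)-yl)propyl)morpholine",20567796,005-912-631,N1(CCOCC1)CCCN2CNC3=NC(N4C(N3C2)N=C5C=CC=CC45)C6=CC=CC=N6,,,,FALSE,FALSE,FALSE
21,"N-((1-(5-(4-benzylpiperazin-1-yl)-1,3,4-thiadiazol-2-yl)-1H-pyrrol-2-yl)methyl)-2-(pyrrolidin-1-yl)ethan-1-amine",20576334,007-776-896,N1(CCCC1)CCNCC2=CC=CN2C3=NN=C(N4CCN(CC4)CC5=CC=CC=C5)S3,,,,TRUE,FALSE,FALSE
22,4-(2-(3-(3-(isoquinolin-4-yl)phenyl)-1H-pyrazol-1-yl)ethyl)morpholine,23213965,005-039-609,N1(C=CC(C2=CC=CC(C3=CN=CC4=CC=CC=C34)=C2)=N1)CCN5CCOCC5,,,,TRUE,TRUE,TRUE
23,"1-(4-(6-(1H-imidazol-1-yl)-2-methylpyrimidin-4-yl)piperazin-1-yl)-2,2-diphenylethan-1-one",65362307,016-587-938,CC1=NC(N2C=CN=C2)=CC(N3CCN(C(C(C4=CC=CC=C4)C5=CC=CC=C5)=O)CC3)=N1,4.01,14.8,9.27,TRUE,TRUE,TRUE
24,1-(6-(1H-pyrazol-1-yl)pyrimidin-4-yl)-N-benzyl-N-(pyridin-2-yl)piperidine-3-carboxamide,70638100,019-920-623,O=C(N(C1=CC=CC=N1)CC2=CC=CC=C2)C3CCCN(C4=CC(N5C=CC=N5)=NC=N4)C3,,,,TRUE,TRUE,TRUE
25,"3-(2-(4-(6-fluorobenzo[d]isoxazol-3-yl)piperidin-1-yl)-2-oxoethyl)-2-hydroxy-3,4-dihydro-5H-benzo[e][1,4]diazepin-5-one",95474733,027-849-694,OC1=NC2=C(C(NC1CC(N3CCC(C4=NOC5=C4C=CC(F)=C5)CC3)=O)=O)C=CC=C2,,,,FALSE,FALSE,TRUE
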