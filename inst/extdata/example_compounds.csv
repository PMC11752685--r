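name,ID,SMILES,Doses max,Activity,FUB,CLint
chlorpromazine,SYNEX001,CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21,200,1,0.04,12
troglitazone,SYNEX002,Cc1c(C)c2CCC(C)(COc3ccc(CC4SC(=O)NC4=O)cc3)Oc2c(C)c1O,600,1,0.02,25
bosentan,SYNEX003,CC(C)(C)c1ccc(cc1)S(=O)(=O)Nc1ncnc(OCCO)c1Oc1ccccc1OC,500,1,0.02,8
metformin,SYNEX004,CN(C)C(=N)NC(N)=N,2550,0,0.99,0.1
caffeine,SYNEX005,Cn1cnc2c1c(=O)n(C)c(=O)n2C,400,0,0.65,3.2
ibuprofen,SYNEX006,CC(C)Cc1ccc(cc1)C(C)C(=O)O,1200,,0.01,15
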