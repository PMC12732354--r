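"sense","antisense","sense_mods","antisense_mods","efficacy","concentration","duration","assay_type","cell_or_organism","transfection_method","gene_id"
"GGAUGAAGUGGAGAUUAGUUU","ACUAAUCUCCACUUCAUCCUU","1:2OMe;21:dT","20:dT;21:dT","82.5","10 nM","24h","qPCR","HeLa","lipofection","SSB"
"CGUACGCGGAAUACUUCGAUU","UCGAAGUAUUCCGCGUACGUU","","2:2'-fluoro","64","25","48 hours","luciferase","HEK293","lipofection","SOD2"
"AUGGCUACGAUCGUAAGCCUU","GGCUUACGAUCGUAGCCAUUU","5:LNA","","IC50","10","24","qPCR","HeLa","electroporation","STAT1"
"GCAAGCUGACCCUGAAGUUCU","GAACUUCAGGGUCAGCUUGCU","","","38","150 nM","24h","western","A549","lipofection","SSB"
"UUCGAAAUGUCCGUUCGGUUU","ACCGAACGGACAUUUCGAAUU","3:inverted abasic","","21","5","3 days","qPCR","HeLa","lipofection","SOD2"
"CACGUACGCGGAAUACUUCGA","UCGAAGUAUUCCGCGUACGUG","","","91","1","24h","qPCR","","lipofection","STAT1"
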