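>SSB
AUGGCGGAAGUUGAAGCUGAACCUGAAGUGGAGAUUAGUCCGACGUAUCGGAUGAAGUGG
AGAUUAGUUUCCGUUACGGAAGCUGACCCUGAAGUUCUGGCAAGCUGACCCUGAAGUUCU
>SOD2
AUGUUGAGCCGGGCAGUGUGCGGCACCAGCAGGCAGCUGGCUCCGGCUUUGGGGUCUUCG
AAAUGUCCGUUCGGUUUCCGUACGCGGAAUACUUCGAUUGGCUUACGAUCGUAGCCAUUU
>STAT1
AUGUCUCAGUGGUACGAACUUCAGCAACUGGACUCAAAAUUCCUGGAGCAGGUUCACCAG
CACGUACGCGGAAUACUUCGAAUGGCUACGAUCGUAAGCCUUGGCUUACGAUCGUAGCCA
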