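>synth_rRNA_1|rRNA
GAUCGCGAUCCAUACGACAAAACGUAUAGUUCAUCGAGAACAAUCACAAAGCCGCGAGCCAGUUUUCCCCAUGCUUAAUUGCUUAACUCCUGAUCUAUACCAGUUCGCGAGAGCAGUACGCUUACACUGGCUUCCACCCUGUUGAUUUAAAAAAAAUCAC
>synth_rRNA_2|rRNA
ACUGUCCGGUGAUAACCUGGCCGGAUAGCCUCCCUCUUCAAAACCUGGUGACCCGCAGCUCUCCUGCGGCGAGUUAUGGCUGGUGUUACGAGUGGUCUGCAGUCGUGCUCAGGUGAAUGUGCGUCCCCUCCCCCGAGAUC
>synth_tRNA_1|tRNA
GCUAUUGUAACUACGCGACUCUGGCUUUAACCGUUGUGUCGUAUGCUGCGCGAGAGGAAAAGAUUGGGCUGUAGCGGGAGCCAUAAUGCU
>synth_tRNA_2|tRNA
GGGCUACCUCCACACCAACGGCACAGCUAGGACGGAACAAUUUUAACACGUUCUAUGAACAGGAGUUGCUGUGAUCGGAGCUAAA
>synth_snRNA_1|snRNA
GUCACCGUACCCUAGAGGUCGCGACCUUGUGGCUCACCCCGCCCAACGGUGCAUCUACUCGAUGUCGUCGAUUUUUACAUGACUGAGCGGAGCUGCGGCUGUCCGGGUGCCUCUGCUGCG
>synth_snRNA_2|snRNA
CUGGUGGACACUGAAAAAUCUAGUGUUCCGUCUCGUCCUCAUAUAUGCAAGGCCCAAUGUCAGCGCAACUCGGCGUGGUAAGACUACGACUUAUUAGUAACAACAGGAUU
>synth_snoRNA_1|snoRNA
GUGAAACUUUAGGAAGUUCUUAUUUCAAAGCUGGUCUGAGACGAAAUAGUCCUACCUUAUCAAGAGUACUAUAACGCGGUGAUAAAGGGAGUUGCAUUUG
>synth_snoRNA_2|snoRNA
AUGGACAGAUAAGUGUGACACCGUUAUUCUCAGGGUCCUCUGUUAAAAGGCAAUGCGUAUUUAGUCUUAGGUAUGAAGGCUUGUGAGGAGGGUCC
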