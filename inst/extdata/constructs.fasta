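>g0001
UUGAGCCGAGGCGCGGCUGACUAAAAUGCAACAUCUCCAAGGAGCACCCGUUGCACCACUAGUGUAUGCU
GAAAUGAUCCAAGGUUGCUACACACGAAUGAUGGACCACACCCGAGGGUACCAUCUGAAGCUAACAUGAU
UGCGUGCAUGUUAGGAAAUCCCGCGCGCCAAUUAAGGAUCUUUGCAAUUGGGUGCUGAGGCUGAUUACAG
CUAGCGGGAUUAGCGCCUAGUACGCUCUGGAUCACCAUUAUAGAGGGAAGGUGAACACGUUUGUUCUAUC
GCUCCUGCUUCGAAUCAAUUCCAGGGACACCCGUGGGUUGGAACAUGCAAUCGACCCAGCAGGACGAACA
UAGAUCAGCUAGUGUCAACUUAUGUUUGCCGAAUACAGGCGGCUUGGAGAAAGUGGUUCAUUAUGGUGAU
ACGGUUAAAUUUGGCAUAGGUAUAUAUGACCAGAGUAGGCCAAGACUAGCAAGAACCGGAGCUUUGGUUG
AGGGUAAAAU
>g0002
UCACUGAAGCGCUGACUGGACAAAACACAGUGCCGCAUGUAGAACAGAUCUUCAGUCCAGUCACUUAGCA
UAAUGUUCACCAUCAGUUUGUAACUUUGGUCACCGAAUGUAACGAAGGUAGGCGACACUGGUUGAGAAGU
UCAGCGACCAUUCUUUGGUAAGAGAUGACUAAGAUAUAGACGAGGUAACUAGAAAGAAUGCUGGCGCGGU
UGCAUCUUACACGCGAUUAGGAAUCGGGUAUCGCCGAUUAUAGAGUCUGGGCUAGGUCGUUCAGUCUGCG
CUCCACCUAGUCCCGCAUCCCAAAUGCGAAAUUACUGGGGCGGAAGGCCGACUAUUAUCUUCUUAAAUCG
CGGAUAAAGUCCGGUUUCGUAUACAAUAGGCGUGAUGAUCACGAGACAUCCCUGUACAAUGCUGUCUAAG
GGUGGGGCGGCCUGAAAUCCGAACUUUGGUGAAGUCGCUGCAUUACAUAAGCCCAGACUGUGACUCCCUU
AUUCCGGCGA
>g0003
GACUUGCAGGCUGCAUUUCGGAGCAUCUCUAAAUAGACAUUUUGUAUUACAUUACUCUCUCUACAUCGAA
AGGAGUGGGGACCAUAUGGAGCCACGGUUUUCCCCCCGAUUGUGUGAGUCAGAUGUUGUACGGGUGAAUC
UGGAUCCAGCGGCAAGUUUCAAUACCGUAAGAGUAAUGCUAUCUAGGGCUUCCGGACAAGUUGGUAACUA
GUCGCUGGAUGCUAUUCUGGAAACAACGAUAGGCAAGUCUACCAGGACCAAGGUGUUAUGACAUACGGAA
UGACCAAGGUGACUUCACGCCCUGGCGCUACAUAACGCAUGUAUCUUGUUCAGUCGCGUAUAAAGGAGCG
GUACGACGAAGAGUACAUAUAUUAAGAAACGCCUUUGAAGGCGCACCCUCAAAUAAAAUCACUUACCUCA
CUGGAUCGAGGUGUCCAGCGAGAGUAACAGUUUCCAUAACCGGUCCAAACAUUAUAGGUCUUCUGGUUUC
CGUUGACAUC
>g0004
CAACACAGUGGCUGAUUUGACCGAGGUAUGAGCCCGGGCCCUGGGGGCUCAGGGCCGCCCGACGUGUUGU
CUAGCCAAGCCUAUUUAGUAAUUACGGUGAUGUCAUCAUUUUGGUAAGGGAAUGCAGCAGGUGCGGCUUU
AGCAUGACUUUAACGUAACAGAUUCGCGAUAUAUGCGGGUACGUUAAUGCCAGGCUCUGUGCAACUAAAC
CCAAUAGGGCCGUUGACUGUAUUCAAGUAGAUACAAAUUAUAGAGACCCGUGGGCUCCGCAGAGCACAUU
UGAGUAAGGGGGACGUUUUAAUUAUUAGAGGGUUGUGAUGGUCGGUGGGAGGUCUACCGAAAAGUUGGAC
UACAAUGAUUCGGGGGGUACAUGGAUCCAUUGUGUCCGUUUUAGUUGGAUCGAUAACUUUACUAGCCUGG
UAUGUCGGAGAUCGCGCGGGUUGAGGCUCAGAAGGGGCACUCGAUCAUAGAGCGACGUCGGACCACCGGC
AGUGUUGGGC
>g0005
GCAGAGGCAAGGGACCGUCCAGGCCCUACAAGUCAACCCGCCAAGCUACUACGAUCCGUGAGAUAAUUGU
UUUGCUCCUAAGUUCAUCACACCGGCAGUUGGAUGCGGAUUCCAUAUUUGACAGUAGGUUGUAUGUGUGC
UGGCGCAGCGUCCCGGCUUUGUCUAAUCAUUAAUAUUAUAGAUGAAAUCAGGGGAUUAAAAAGCCGUGUU
UCGAGCUCGAUCGGACAGGUGUCUUUGAAUGAAGAGUAUUCGACUCUCCCAGUAAAUUCAACUACGAAUA
CCGUCGUGUCGCUUUAGAACAGUCCCGUAUGGUUUGCAUCCAACACAGUGGUCGGAGACCGGAUCGGUAU
UCACGCCCCCGGAGUGCAGUGUUCAUAGAUCGGCUAGAACAGCGGAUCACGCAGGGUUCUUUUGUUCUCC
CUAACUAGCUUACGGCGUCUGAUAGUGGUAAGGUGUACAUUCACGACUUUAAAAGGGGAUCCGCACCCAA
CUAACUUCGC
>g0006
CUGCAUUCGGAACAACGCCAACCAACUUAACGCGCUGGCUUGGUUAUUGAUUGGGCCAGGCUCCACUUGC
CGUAAGAUCACGUAUCCGCGGCCGAGGUGGCCAGACUGGUCAGGAGGAAGGUUAUUAGCACCCCACCGUC
GGAGGGUCCGCGGAAAUAAAGGCCUCGACAGUUAGGCGUGGCGGUGCCAGAGAUUGGAGCCAACAAAAAA
CACGCAACGUGACUCUGAAAUUUCAUGACACGGUAAAUUAUAGCGAGUAAUAACUACAUAGACAGUCUUU
AGUAGGCUAUCACCUGGGGGUUGUAACUCCACCUUUAUCUCUGGCUUUCAUGCUCAUCAGUUAGUACUUA
CGCUUAGGGUUCAUUCCGCAGGUUGCUGCCGCCUGUAUAGUGCUGGGCUCUCACGUGGAGCCAUCAGAAC
UAGGCGUUGACCUUCGUCAUAUCGGACUUAAUUAAGUUAGUCUCUUUGACAUUCCCUCGGCCGGUGCAUG
AUCCCGCCGG
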