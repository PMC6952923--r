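>mir-sim-0001
CACGUCGCGGCCGCGCCUACUC
>mir-sim-0002
UGCGAGGAGGCCAGUCAU
>mir-sim-0003
AAUUUCACGAUGGCUGUU
>mir-sim-0004
AGUACUUUCACAAACAUACCAUA
>mir-sim-0005
GGGAGUGCAGCCCUUGUGACGC
>mir-sim-0006
CUCCAGCUAGCGGCGGUCCACCUU
>mir-sim-0007
GUGUUACCUUCCCAUAUGUA
>mir-sim-0008
CCUACCGCGGCAUGACUAAAU
>mir-sim-0009
CGAUGGACCGGCCAGGCUUCA
>mir-sim-0010
UGAGUCAAUUCCCAUCCCGCUCUGA
>mir-sim-0011
UCCCGCGGAUACCAAUAAUUAG
>mir-sim-0012
CCUGGUGCUAAUGUAGUCGUUUGG
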