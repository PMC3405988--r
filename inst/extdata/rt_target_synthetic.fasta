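>RT_synthetic synthetic stand-in for the Q-beta RT reporter (genomic 1743-2333); generated by synthetic_rt_target()
UGAUUUGUUCUAAUACUCGGUGGUAGCCGUGCGUGCCUGGCACGAGGCCUCGUGGUAAGA
CCUUUUAUAGAUGCCCCCAUAGAGACAGUGCUUAGGCACGGGCCCUUAAUGGAAAUCUCC
CUACGACCCGGCCGUCGUACCCACGGUAUGGGCUCGGUGCUUCGCGUGUACAUUGUGAUU
GCACGUGAUAUCGAUAGUUUAUGUUCUAUGCUCAAAGAGAUUUUAGGAUUAUAUGUUGUC
AGGGGUUGGGUCACUCGACUUCGGCAAAGUUCUAUAGAUCGGUGCGACCGAAUUAUUUUG
GCGCCACUAGCAUAUGACUACCAGCUUGUGCCUGUGAGAUGCGAGUUCAUGCACACAUGU
CCCCCCGAAAUGUGUAGUCGUGGCGAAUUCAUGAGUUUCCCCGGUCCGAUUAAUCUUAAG
UACGAUUUAGCACGCUACUCACUCAUGGACACUCCUCUCUACAGGAUGUUCGGCUUGAUA
UUUACUUGUCACAUUGUAUACGUGGCGAUUAUAGUAUGCAAUGAUGACACCAGACUUUCC
CGACAAGAGGUACUUUUUGCCGAAGCAUCGUCUGCCAUUGGAGCUGUCUAG
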