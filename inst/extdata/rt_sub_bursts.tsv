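# Single-burst reversion test of the stop-codon substitution mutant
# (RT_SUB): revertants per plated culture after removal of one large
# burst attributed to a preexisting revertant (498 cultures retained).
# Metadata: N = 35 infected cells per culture, burst size B = 859 +/- 165.
revertants	cultures
0	238
1	150
2	66
3	27
4	10
5	2
6	3
7	1
8	1
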