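# Single-burst reversion test of the four-base-insertion mutant (RT_IN):
# revertants per plated culture after removal of five large bursts
# attributed to preexisting revertants (239 cultures retained).
# Metadata: N = 4560 infected cells per culture, burst size B = 328 +/- 93.
revertants	cultures
0	31
1	63
2	55
3	49
4	24
5	11
6	4
7	1
8	1
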