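# Spontaneous RT mutations recovered from the Q-beta plaque screen:
# 45 mutations (32 primary + 13 secondary) in 32 isolates.
# Columns: 1-based target position; kind; wild-type and mutant bases
# ((+) strand); inserted/deleted residues for indels; primary mutations
# were detected by phenotype, secondary (hitchhiker) mutations were
# found in next-generation sub-isolates. The impact column gives the
# coding effect (amino acids for substitutions); for the two synonymous
# substitutions whose codons are not published (RT24, RT35) the amino
# acid is a synthetic choice consistent with the synonymous effect.
isolate	position	kind	wt	mut	indel_seq	rank	impact
RT1	383	substitution	G	U	NA	primary	Gly>Val
RT1	13	substitution	A	G	NA	secondary	Ile>Val
RT3	449	substitution	A	G	NA	primary	Asp>Gly
RT4	122	substitution	U	C	NA	primary	Leu>Pro
RT4	473	substitution	G	A	NA	secondary	Gly>Asp
RT5	383	substitution	G	A	NA	primary	Gly>Asp
RT5	283	substitution	U	G	NA	secondary	Cys>Gly
RT6	260	substitution	U	C	NA	primary	Leu>Pro
RT7	526	substitution	G	U	NA	primary	Asp>Tyr
RT10	249	substitution	G	A	NA	primary	Trp>Stop
RT14	388	substitution	U	C	NA	primary	Phe>Leu
RT14	411	substitution	U	C	NA	secondary	Ile>Ile
RT16	430	substitution	G	A	NA	primary	Ala>Thr
RT18	119	substitution	C	U	NA	primary	Ser>Phe
RT18	527	substitution	A	G	NA	primary	Asp>Gly
RT20	460	substitution	U	C	NA	primary	Tyr>His
RT21	170	substitution	A	G	NA	primary	Tyr>Cys
RT23	221	insertion	NA	NA	U	primary	Frameshift
RT23	85	substitution	A	U	NA	secondary	Thr>Ser
RT25	449	substitution	A	G	NA	primary	Asp>Gly
RT26	11	substitution	U	C	NA	primary	Leu>Pro
RT27	261	substitution	U	C	NA	primary	Leu>Leu
RT27	478	substitution	A	G	NA	secondary	Ile>Val
RT29	389	substitution	U	C	NA	primary	Phe>Ser
RT31	367	substitution	G	A	NA	primary	Glu>Lys
RT31	21	substitution	U	C	NA	secondary	Gly>Gly
RT32	479	substitution	U	C	NA	primary	Ile>Thr
RT32	105	substitution	C	U	NA	secondary	Pro>Pro
RT33	382	substitution	G	A	NA	primary	Gly>Ser
RT33	442	substitution	C	U	NA	secondary	Leu>Phe
RT36	439	substitution	U	C	NA	primary	Ser>Pro
RT37	106	insertion	NA	NA	U	primary	Frameshift
RT40	2	substitution	G	A	NA	primary	Stop>Stop
RT40	213	substitution	C	U	NA	secondary	Leu>Leu
RT40	216	substitution	A	G	NA	secondary	Lys>Lys
RT41	24	substitution	U	C	NA	primary	Gly>Gly
RT41	565	substitution	G	A	NA	primary	Ala>Thr
RT42	68	substitution	U	C	NA	primary	Ile>Thr
RT43	430	substitution	G	A	NA	primary	Ala>Thr
RT44	283	substitution	U	C	NA	primary	Cys>Arg
RT45	308	substitution	U	C	NA	primary	Leu>Pro
RT46	248	substitution	G	A	NA	primary	Trp>Stop
RT47	449	substitution	A	G	NA	primary	Asp>Gly
RT24	18	substitution	C	U	NA	secondary	Leu>Leu
RT35	294	substitution	U	C	NA	secondary	Ile>Ile
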