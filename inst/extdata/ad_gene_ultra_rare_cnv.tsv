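chrom	pos	end	svtype	ac_case	ac_control	gene	protein_altering
chr19	1050368	1050973	DEL	4	0	ABCA7	TRUE
chr16	81775821	81829769	DEL	4	0	PLCG2	TRUE
chr19	1052156	1060559	DUP	3	1	ABCA7	TRUE
chr16	81860089	81940500	DEL	3	0	PLCG2	TRUE
chr2	127094683	127094740	DEL	2	1	BIN1	FALSE
chr7	100296733	100385675	DEL	2	0	PILRA	TRUE
chr16	81907252	81907401	DEL	2	0	PLCG2	FALSE
chr14	92611452	92611515	DEL	2	0	RIN3	FALSE
chr19	1043504	1053484	DEL	1	0	ABCA7	TRUE
chr19	1054326	1061615	DUP	1	0	ABCA7	TRUE
chr15	58720431	58721649	DEL	1	0	ADAM10	FALSE
chr21	25815144	26232105	DUP	1	0	APP	TRUE
chr21	25958556	25971275	DEL	1	0	APP	FALSE
chr21	26163874	26163976	DUP	1	0	APP	FALSE
chr2	127102503	127104954	DEL	1	0	BIN1	FALSE
chr10	113725274	113726288	DEL	1	0	CASP7	TRUE
chr11	60138757	60178011	DEL	1	1	MS4A6A	TRUE
chr11	60179765	60450406	DUP	1	0	MS4A6A	TRUE
chr11	86050643	86054032	DEL	1	0	PICALM	FALSE
chr16	81734058	81749307	DEL	1	0	PLCG2	TRUE
chr16	81749081	81749132	DEL	1	0	PLCG2	FALSE
chr16	81755550	81764402	DEL	1	0	PLCG2	TRUE
chr16	81772599	81777744	DEL	1	0	PLCG2	TRUE
chr16	81792449	81792587	DEL	1	0	PLCG2	FALSE
chr16	81798030	81802305	DEL	1	1	PLCG2	TRUE
chr16	81822810	81822862	DEL	1	0	PLCG2	FALSE
chr16	81868226	81868350	DEL	1	1	PLCG2	FALSE
chr14	92369331	92644481	DUP	1	0	RIN3	TRUE
chr14	92531510	92573409	DUP	1	0	RIN3	TRUE
chr11	121303351	121495669	DUP	1	0	SORL1	TRUE
chr11	121490959	121499413	DEL	1	0	SORL1	TRUE
chr19	1051380	1051420	DEL	0	1	ABCA7	FALSE
chr15	58621731	58622007	DUP	0	1	ADAM10	FALSE
chr19	44909364	44909819	DUP	0	1	APOE	TRUE
chr21	26013065	26013159	DEL	0	1	APP	FALSE
chr2	127064222	127064288	DEL	0	1	BIN1	FALSE
chr2	127092466	127092526	DEL	0	1	BIN1	FALSE
chr2	127094016	127102983	DEL	0	1	BIN1	FALSE
chr1	207604022	207605343	DEL	0	1	CR1	FALSE
chr7	100377717	100378235	DEL	0	1	PILRA	FALSE
chr16	81746327	81746435	DEL	0	1	PLCG2	FALSE
chr16	81885235	81893072	DEL	0	1	PLCG2	TRUE
chr14	73215181	73313643	DEL	0	1	PSEN1	TRUE
chr14	92535796	92535871	DEL	0	1	RIN3	FALSE
chr14	92605335	92607867	DEL	0	1	RIN3	FALSE
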