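family	mirna_id	mature_seq	mismatch	delta_g_mag	mfei
mir477	mes-miR477h	ACUCUCCCUCAAGGGCUUCAG	4	82.6	0.77
mir319	ath-miR319a	UUGGACUGAAGGGAGCUCCCU	2	116.2	0.83
mir396	cca-miR396c	UUCAAGAAAGCUGUGGGAAAA	1	117.3	0.77
mir159	pde-miR159	UUUGGUUUGAAGGGAGCUCUA	4	116.5	0.74
mir828	vvi-miR828a	UCUUGCUCAAAUGAGUAUUCCA	3	102	0.71
mir171	ctr-miR171	UUGAGCCGCGUCAAUAUCUCC	1	125.80	0.73
mir167	ath-miR167d	UGAAGCUGCCAGCAUGAUCUGG	2	105.60	0.71
mir4376	sly-miR4376	ACGCAGGAGAGAUGAUGCUGGA	5	109.6	0.81
mir169	gma-miR169d	UGAGCCAAGGAUGACUUGCCGGU	4	98.1	0.77
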