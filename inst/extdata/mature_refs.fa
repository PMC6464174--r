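>mes-miR477h
ACUCUCCCUCAAGGGCUUCAG
>ath-miR319a
UUGGACUGAAGGGAGCUCCCU
>cca-miR396c
UUCAAGAAAGCUGUGGGAAAA
>pde-miR159
UUUGGUUUGAAGGGAGCUCUA
>vvi-miR828a
UCUUGCUCAAAUGAGUAUUCCA
>ctr-miR171
UUGAGCCGCGUCAAUAUCUCC
>ath-miR167d
UGAAGCUGCCAGCAUGAUCUGG
>sly-miR4376
ACGCAGGAGAGAUGAUGCUGGA
>gma-miR169d
UGAGCCAAGGAUGACUUGCCGGU
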