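# Response-element grammar: LABEL<TAB>NOTATION
# Half-sites and dyads of the thyroid hormone receptor, plus two putative
# negative-element sequences. Dyad notation: LEFT-spacer-RIGHT.
Halfsite	AGGTCA
Halfsite_deg	AGGnCA
DR4	AGGnCA-4-AGGnCA
DR4_deg	AGGnnn-4-AGGnCA
ER6	nnnCCT-6-AGGnCA
IP0	nnnCCT-0-AGGnCA
IP1	nnnCCT-1-AGGnCA
Neg1	TTTGGG
Neg2	CCCCTCAGGCGC
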