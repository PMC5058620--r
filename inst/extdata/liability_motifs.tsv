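name	pattern	regions	type	note
n_glycosylation	N-X-[ST]	all	pattern	Asn-X-Ser/Thr sequon
deamidation	N-[GS]	all	pattern	Asn deamidation
asp_isomerization	D-[GSTD]	all	pattern	Asp isomerization
met_oxidation	M	all	pattern	Met oxidation (if exposed)
trp_oxidation	W	all	pattern	Trp oxidation (if exposed)
pyroglutamate	[EQ]	all	nterm	N-terminal Glu/Gln cyclization
lysine_glycation	K-[KE]	all	pattern	Lys glycation context
unpaired_cysteine	C	all	unpaired_cys	Cys outside the conserved intra-domain pair
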