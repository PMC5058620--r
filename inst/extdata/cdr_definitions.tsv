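scheme	chain	cdr	start	end
north	H	1	26	33
north	H	2	50	59
north	H	3	99	110
north	L	1	24	34
north	L	2	50	56
north	L	3	89	97
chothia	H	1	27	32
chothia	H	2	51	56
chothia	H	3	99	110
chothia	L	1	24	34
chothia	L	2	50	56
chothia	L	3	89	97
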