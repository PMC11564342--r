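pathway	gene
WNT	APC
WNT	CTNNB1
WNT	AXIN1
WNT	AXIN2
WNT	SOX9
WNT	RNF43
WNT	AMER1
WNT	TCF7L2
WNT	LRP5
WNT	LRP6
WNT	GSK3B
RTK-RAS	KRAS
RTK-RAS	NRAS
RTK-RAS	HRAS
RTK-RAS	BRAF
RTK-RAS	EGFR
RTK-RAS	ERBB2
RTK-RAS	ERBB3
RTK-RAS	ERBB4
RTK-RAS	MAP2K1
RTK-RAS	MAP2K4
RTK-RAS	NF1
RTK-RAS	PTPN11
RTK-RAS	MET
RTK-RAS	RET
RTK-RAS	NTRK1
RTK-RAS	NTRK3
PI3K	PIK3CA
PI3K	PIK3R1
PI3K	PTEN
PI3K	AKT1
PI3K	AKT2
PI3K	MTOR
PI3K	TSC1
PI3K	TSC2
PI3K	STK11
PI3K	INPP4B
TP53	TP53
TP53	MDM2
TP53	MDM4
TP53	ATM
TP53	CHEK2
TP53	RPS6KA3
Cell-Cycle	CDKN2A
Cell-Cycle	CDKN2B
Cell-Cycle	CDKN1A
Cell-Cycle	CDKN1B
Cell-Cycle	CCND1
Cell-Cycle	CCNE1
Cell-Cycle	CDK4
Cell-Cycle	CDK6
Cell-Cycle	RB1
Myc	MYC
Myc	MYCN
Myc	MYCL
Myc	MXD1
Myc	MAX
Myc	MGA
Notch	NOTCH1
Notch	NOTCH2
Notch	NOTCH3
Notch	NOTCH4
Notch	FBXW7
Notch	CREBBP
Notch	EP300
Notch	SPEN
Hippo	FAT1
Hippo	NF2
Hippo	LATS1
Hippo	LATS2
Hippo	SAV1
Hippo	TAOK1
Hippo	YAP1
Hippo	WWTR1
TGF-Beta	TGFBR1
TGF-Beta	TGFBR2
TGF-Beta	SMAD2
TGF-Beta	SMAD3
TGF-Beta	SMAD4
TGF-Beta	ACVR2A
TGF-Beta	ACVR1B
Nrf2	NFE2L2
Nrf2	KEAP1
Nrf2	CUL3
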