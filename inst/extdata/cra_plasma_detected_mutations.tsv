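gene	variant_class	protein_change	vaf	patient_id
NOVA1	intron	/	2.87	P9
KRAS	missense	p.G12V	0.92	P8
CCDC170	intron	/	9.38	P7
KIF1B	intron	/	2.97	P6
BAP1	intron	/	2.41	P6
APC	frameshift	p.G1394fs	0.94	P5
KRAS	missense	p.G12V	1.57	P5
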