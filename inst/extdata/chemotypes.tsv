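resname	atom	role	hyb	ideal_d	parent	ref	nbond	h_build
*	N	donor	sp2	2.87	CA	-C	2	backbone_amide
*	O	acceptor	sp2	2.73	C	CA	1	none
*	OXT	acceptor	sp2	2.73	C	CA	1	none
SER	OG	both	sp3	2.73	CB	CA	1	hydroxyl1
THR	OG1	both	sp3	2.73	CB	CA	1	hydroxyl1
TYR	OH	both	sp3	2.73	CZ	CE1	1	hydroxyl1
ASP	OD1	acceptor	sp2	2.73	CG	OD2	1	none
ASP	OD2	acceptor	sp2	2.73	CG	OD1	1	none
GLU	OE1	acceptor	sp2	2.73	CD	OE2	1	none
GLU	OE2	acceptor	sp2	2.73	CD	OE1	1	none
ASN	OD1	acceptor	sp2	2.73	CG	ND2	1	none
ASN	ND2	donor	sp2	2.87	CG	OD1	1	amide2
GLN	OE1	acceptor	sp2	2.73	CD	NE2	1	none
GLN	NE2	donor	sp2	2.87	CD	OE1	1	amide2
LYS	NZ	donor	sp3	2.87	CE	CD	1	amine3
ARG	NE	donor	sp2	2.87	CD	CZ	2	ring1
ARG	NH1	donor	sp2	2.87	CZ	NE	1	amide2
ARG	NH2	donor	sp2	2.87	CZ	NE	1	amide2
HIS	ND1	acceptor	sp2	2.87	CG	CE1	2	none
HIS	NE2	donor	sp2	2.87	CD2	CE1	2	ring1
TRP	NE1	donor	sp2	2.87	CD1	CE2	2	ring1
HOH	O	both	sp3	2.73	-	-	0	none
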