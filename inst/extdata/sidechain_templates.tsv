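resname	atom	a	b	c	bond	angle	torsion
ALA	CB	N	C	CA	1.521	110.5	123.0
SER	CB	N	C	CA	1.530	110.5	123.0
SER	OG	N	CA	CB	1.417	110.8	chi1
THR	CB	N	C	CA	1.540	110.5	123.0
THR	OG1	N	CA	CB	1.433	109.6	chi1
THR	CG2	N	CA	CB	1.521	110.5	chi1-120
CYS	CB	N	C	CA	1.530	110.5	123.0
CYS	SG	N	CA	CB	1.808	114.4	chi1
VAL	CB	N	C	CA	1.540	110.5	123.0
VAL	CG1	N	CA	CB	1.527	110.5	chi1
VAL	CG2	N	CA	CB	1.527	110.5	chi1+122
LEU	CB	N	C	CA	1.530	110.5	123.0
LEU	CG	N	CA	CB	1.530	116.3	chi1
LEU	CD1	CA	CB	CG	1.521	110.7	chi2
LEU	CD2	CA	CB	CG	1.521	110.7	chi2+122
ILE	CB	N	C	CA	1.540	110.5	123.0
ILE	CG1	N	CA	CB	1.530	110.4	chi1
ILE	CG2	N	CA	CB	1.521	110.5	chi1-122
ILE	CD1	CA	CB	CG1	1.513	113.8	chi2
PRO	CB	N	C	CA	1.530	103.0	115.0
PRO	CG	N	CA	CB	1.492	104.5	chi1
PRO	CD	CA	CB	CG	1.503	106.1	chi2
MET	CB	N	C	CA	1.530	110.5	123.0
MET	CG	N	CA	CB	1.520	114.1	chi1
MET	SD	CA	CB	CG	1.803	112.7	chi2
MET	CE	CB	CG	SD	1.791	100.9	chi3
PHE	CB	N	C	CA	1.530	110.5	123.0
PHE	CG	N	CA	CB	1.502	113.8	chi1
PHE	CD1	CA	CB	CG	1.384	120.8	chi2
PHE	CD2	CA	CB	CG	1.384	120.8	chi2+180
PHE	CE1	CB	CG	CD1	1.384	120.8	180
PHE	CE2	CB	CG	CD2	1.384	120.8	180
PHE	CZ	CG	CD1	CE1	1.382	120.0	0
TYR	CB	N	C	CA	1.530	110.5	123.0
TYR	CG	N	CA	CB	1.512	113.9	chi1
TYR	CD1	CA	CB	CG	1.389	120.8	chi2
TYR	CD2	CA	CB	CG	1.389	120.8	chi2+180
TYR	CE1	CB	CG	CD1	1.382	121.1	180
TYR	CE2	CB	CG	CD2	1.382	121.1	180
TYR	CZ	CG	CD1	CE1	1.378	119.5	0
TYR	OH	CD1	CE1	CZ	1.376	119.9	180
TRP	CB	N	C	CA	1.530	110.5	123.0
TRP	CG	N	CA	CB	1.498	113.6	chi1
TRP	CD1	CA	CB	CG	1.365	126.9	chi2
TRP	CD2	CA	CB	CG	1.433	126.7	chi2+180
TRP	NE1	CB	CG	CD1	1.374	110.2	180
TRP	CE2	CB	CG	CD2	1.409	107.2	180
TRP	CE3	CB	CG	CD2	1.398	133.9	0
TRP	CZ2	CG	CD2	CE2	1.394	122.4	180
TRP	CZ3	CG	CD2	CE3	1.382	118.6	180
TRP	CH2	CD2	CE2	CZ2	1.368	117.5	0
ASP	CB	N	C	CA	1.530	110.5	123.0
ASP	CG	N	CA	CB	1.516	112.6	chi1
ASP	OD1	CA	CB	CG	1.249	118.4	chi2
ASP	OD2	CA	CB	CG	1.249	118.4	chi2+180
ASN	CB	N	C	CA	1.530	110.5	123.0
ASN	CG	N	CA	CB	1.516	112.6	chi1
ASN	OD1	CA	CB	CG	1.231	120.8	chi2
ASN	ND2	CA	CB	CG	1.328	116.4	chi2+180
GLU	CB	N	C	CA	1.530	110.5	123.0
GLU	CG	N	CA	CB	1.520	114.1	chi1
GLU	CD	CA	CB	CG	1.516	112.6	chi2
GLU	OE1	CB	CG	CD	1.249	118.4	chi3
GLU	OE2	CB	CG	CD	1.249	118.4	chi3+180
GLN	CB	N	C	CA	1.530	110.5	123.0
GLN	CG	N	CA	CB	1.520	114.1	chi1
GLN	CD	CA	CB	CG	1.516	112.6	chi2
GLN	OE1	CB	CG	CD	1.231	120.8	chi3
GLN	NE2	CB	CG	CD	1.328	116.4	chi3+180
LYS	CB	N	C	CA	1.530	110.5	123.0
LYS	CG	N	CA	CB	1.520	114.1	chi1
LYS	CD	CA	CB	CG	1.520	111.3	chi2
LYS	CE	CB	CG	CD	1.520	111.3	chi3
LYS	NZ	CG	CD	CE	1.489	111.9	chi4
ARG	CB	N	C	CA	1.530	110.5	123.0
ARG	CG	N	CA	CB	1.520	114.1	chi1
ARG	CD	CA	CB	CG	1.520	111.3	chi2
ARG	NE	CB	CG	CD	1.461	112.0	chi3
ARG	CZ	CG	CD	NE	1.329	124.2	chi4
ARG	NH1	CD	NE	CZ	1.326	120.0	0
ARG	NH2	CD	NE	CZ	1.326	120.0	180
HIS	CB	N	C	CA	1.530	110.5	123.0
HIS	CG	N	CA	CB	1.497	113.8	chi1
HIS	ND1	CA	CB	CG	1.371	122.7	chi2
HIS	CD2	CA	CB	CG	1.356	131.0	chi2+180
HIS	CE1	CB	CG	ND1	1.319	109.2	180
HIS	NE2	CB	CG	CD2	1.374	107.2	180
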