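resname	freq	chi1	chi2	chi3	chi4
ALA	1.00	NA	NA	NA	NA
GLY	1.00	NA	NA	NA	NA
SER	0.48	64	NA	NA	NA
SER	0.29	-65	NA	NA	NA
SER	0.23	180	NA	NA	NA
CYS	0.55	-65	NA	NA	NA
CYS	0.26	180	NA	NA	NA
CYS	0.19	64	NA	NA	NA
THR	0.49	62	NA	NA	NA
THR	0.44	-60	NA	NA	NA
THR	0.07	180	NA	NA	NA
VAL	0.73	175	NA	NA	NA
VAL	0.21	-64	NA	NA	NA
VAL	0.06	63	NA	NA	NA
LEU	0.62	-65	175	NA	NA
LEU	0.30	177	65	NA	NA
LEU	0.08	-85	65	NA	NA
ILE	0.61	-65	170	NA	NA
ILE	0.16	-57	-60	NA	NA
ILE	0.13	62	170	NA	NA
ILE	0.10	180	165	NA	NA
PRO	0.55	27	-35	NA	NA
PRO	0.45	-27	35	NA	NA
MET	0.28	-65	-65	-70	NA
MET	0.25	-65	180	75	NA
MET	0.22	180	180	75	NA
MET	0.15	-65	180	180	NA
MET	0.10	180	65	75	NA
PHE	0.46	-65	90	NA	NA
PHE	0.35	180	80	NA	NA
PHE	0.13	63	90	NA	NA
PHE	0.06	-85	-30	NA	NA
TYR	0.46	-65	90	NA	NA
TYR	0.35	180	80	NA	NA
TYR	0.13	63	90	NA	NA
TYR	0.06	-85	-30	NA	NA
TRP	0.35	-65	95	NA	NA
TRP	0.25	180	-105	NA	NA
TRP	0.20	-65	-90	NA	NA
TRP	0.12	180	90	NA	NA
TRP	0.08	62	-90	NA	NA
HIS	0.32	-63	-75	NA	NA
HIS	0.25	180	75	NA	NA
HIS	0.20	-65	165	NA	NA
HIS	0.13	62	-75	NA	NA
HIS	0.10	180	-165	NA	NA
ASP	0.51	-70	-15	NA	NA
ASP	0.29	180	15	NA	NA
ASP	0.20	62	15	NA	NA
ASN	0.40	-65	-40	NA	NA
ASN	0.26	180	60	NA	NA
ASN	0.19	-65	120	NA	NA
ASN	0.15	62	-20	NA	NA
GLU	0.35	-67	180	-10	NA
GLU	0.25	180	180	0	NA
GLU	0.18	-67	-65	-10	NA
GLU	0.12	-80	80	0	NA
GLU	0.10	62	180	0	NA
GLN	0.35	-67	180	20	NA
GLN	0.25	180	180	0	NA
GLN	0.20	-67	-65	-20	NA
GLN	0.20	62	180	20	NA
LYS	0.28	-67	180	180	180
LYS	0.22	180	180	180	180
LYS	0.18	-67	180	180	-65
LYS	0.17	-67	-65	180	180
LYS	0.15	180	65	180	180
ARG	0.27	-67	180	180	180
ARG	0.22	180	180	180	180
ARG	0.20	-67	-167	180	180
ARG	0.16	-67	180	65	85
ARG	0.15	62	180	180	180
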