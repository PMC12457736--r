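resname	atomname	element	radius
*	*	C	1.87
*	*	N	1.65
*	*	O	1.4
*	*	S	1.85
*	*	SE	1.9
*	*	P	1.9
*	C	C	1.76
PHE	CG	C	1.76
PHE	CD1	C	1.76
PHE	CD2	C	1.76
PHE	CE1	C	1.76
PHE	CE2	C	1.76
PHE	CZ	C	1.76
TYR	CG	C	1.76
TYR	CD1	C	1.76
TYR	CD2	C	1.76
TYR	CE1	C	1.76
TYR	CE2	C	1.76
TYR	CZ	C	1.76
TRP	CG	C	1.76
TRP	CD1	C	1.76
TRP	CD2	C	1.76
TRP	CE2	C	1.76
TRP	CE3	C	1.76
TRP	CZ2	C	1.76
TRP	CZ3	C	1.76
TRP	CH2	C	1.76
HIS	CG	C	1.76
HIS	CD2	C	1.76
HIS	CE1	C	1.76
ARG	CZ	C	1.76
ASP	CG	C	1.76
GLU	CD	C	1.76
ASN	CG	C	1.76
GLN	CD	C	1.76
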