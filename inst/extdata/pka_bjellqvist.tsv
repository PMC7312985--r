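# Bjellqvist pKa set: residue-specific N-terminal amine pKa, common C-terminal
# carboxyl pKa with side-chain adjustments for C-terminal Asp/Glu, and
# side-chain pKa values. charge: +1 basic (cationic when protonated),
# -1 acidic (anionic when deprotonated).
group	key	pka	charge
nterm	default	7.50	1
nterm	A	7.59	1
nterm	M	7.00	1
nterm	S	6.93	1
nterm	P	8.36	1
nterm	T	6.82	1
nterm	V	7.44	1
nterm	E	7.70	1
nterm	G	7.50	1
cterm	default	3.55	-1
cterm_sidechain	D	4.55	-1
cterm_sidechain	E	4.75	-1
sidechain	D	4.05	-1
sidechain	E	4.45	-1
sidechain	C	9.00	-1
sidechain	Y	10.00	-1
sidechain	H	5.98	1
sidechain	K	10.00	1
sidechain	R	12.00	1
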