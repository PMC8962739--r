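residue	hydrophobicity	charge	binding_probability
ALA	1.8	0	0.07
ARG	-4.5	1	0.12
ASN	-3.5	0	0.11
ASP	-3.5	-1	0.10
CYS	2.5	0	0.15
GLN	-3.5	0	0.09
GLU	-3.5	-1	0.08
GLY	-0.4	0	0.07
HIS	-3.2	0	0.20
ILE	4.5	0	0.14
LEU	3.8	0	0.13
LYS	-3.9	1	0.07
MET	1.9	0	0.18
PHE	2.8	0	0.21
PRO	-1.6	0	0.05
SER	-0.8	0	0.09
THR	-0.7	0	0.10
TRP	-0.9	0	0.27
TYR	-1.3	0	0.22
VAL	4.2	0	0.10
UNK	0	0	0.00
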