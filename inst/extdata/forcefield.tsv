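# voxmut self-contained nonbonded parameter table, v1.
# Columns: resname  atom  charge(e)  sigma(A)  epsilon(kcal/mol)  vdw_radius(A)
# Per-atom rows give partial charges for the heavy atoms of the 20 canonical
# residues (plus MSE); heavy-atom charges of each residue sum to its formal
# charge. Rows with resname "*" are element-level fallbacks; NA sigma/epsilon/
# vdw_radius on a per-atom row means "use the element fallback".
resname	atom	charge	sigma	epsilon	vdw_radius
*	C	0.000	3.50	0.066	1.70
*	N	0.000	3.25	0.170	1.55
*	O	0.000	2.96	0.210	1.52
*	S	0.000	3.55	0.250	1.80
*	other	0.000	3.55	0.250	1.80
ALA	N	-0.500	NA	NA	NA
ALA	CA	0.500	NA	NA	NA
ALA	C	0.500	NA	NA	NA
ALA	O	-0.500	NA	NA	NA
ALA	CB	0.000	NA	NA	NA
GLY	N	-0.500	NA	NA	NA
GLY	CA	0.500	NA	NA	NA
GLY	C	0.500	NA	NA	NA
GLY	O	-0.500	NA	NA	NA
VAL	N	-0.500	NA	NA	NA
VAL	CA	0.500	NA	NA	NA
VAL	C	0.500	NA	NA	NA
VAL	O	-0.500	NA	NA	NA
VAL	CB	0.000	NA	NA	NA
VAL	CG1	0.000	NA	NA	NA
VAL	CG2	0.000	NA	NA	NA
LEU	N	-0.500	NA	NA	NA
LEU	CA	0.500	NA	NA	NA
LEU	C	0.500	NA	NA	NA
LEU	O	-0.500	NA	NA	NA
LEU	CB	0.000	NA	NA	NA
LEU	CG	0.000	NA	NA	NA
LEU	CD1	0.000	NA	NA	NA
LEU	CD2	0.000	NA	NA	NA
ILE	N	-0.500	NA	NA	NA
ILE	CA	0.500	NA	NA	NA
ILE	C	0.500	NA	NA	NA
ILE	O	-0.500	NA	NA	NA
ILE	CB	0.000	NA	NA	NA
ILE	CG1	0.000	NA	NA	NA
ILE	CG2	0.000	NA	NA	NA
ILE	CD1	0.000	NA	NA	NA
PRO	N	-0.500	NA	NA	NA
PRO	CA	0.500	NA	NA	NA
PRO	C	0.500	NA	NA	NA
PRO	O	-0.500	NA	NA	NA
PRO	CB	0.000	NA	NA	NA
PRO	CG	0.000	NA	NA	NA
PRO	CD	0.000	NA	NA	NA
PHE	N	-0.500	NA	NA	NA
PHE	CA	0.500	NA	NA	NA
PHE	C	0.500	NA	NA	NA
PHE	O	-0.500	NA	NA	NA
PHE	CB	0.000	NA	NA	NA
PHE	CG	0.000	NA	NA	NA
PHE	CD1	0.000	NA	NA	NA
PHE	CD2	0.000	NA	NA	NA
PHE	CE1	0.000	NA	NA	NA
PHE	CE2	0.000	NA	NA	NA
PHE	CZ	0.000	NA	NA	NA
MET	N	-0.500	NA	NA	NA
MET	CA	0.500	NA	NA	NA
MET	C	0.500	NA	NA	NA
MET	O	-0.500	NA	NA	NA
MET	CB	0.000	NA	NA	NA
MET	CG	0.100	NA	NA	NA
MET	SD	-0.200	NA	NA	NA
MET	CE	0.100	NA	NA	NA
CYS	N	-0.500	NA	NA	NA
CYS	CA	0.500	NA	NA	NA
CYS	C	0.500	NA	NA	NA
CYS	O	-0.500	NA	NA	NA
CYS	CB	0.180	NA	NA	NA
CYS	SG	-0.180	NA	NA	NA
SER	N	-0.500	NA	NA	NA
SER	CA	0.500	NA	NA	NA
SER	C	0.500	NA	NA	NA
SER	O	-0.500	NA	NA	NA
SER	CB	0.250	NA	NA	NA
SER	OG	-0.250	NA	NA	NA
THR	N	-0.500	NA	NA	NA
THR	CA	0.500	NA	NA	NA
THR	C	0.500	NA	NA	NA
THR	O	-0.500	NA	NA	NA
THR	CB	0.250	NA	NA	NA
THR	OG1	-0.250	NA	NA	NA
THR	CG2	0.000	NA	NA	NA
ASN	N	-0.500	NA	NA	NA
ASN	CA	0.500	NA	NA	NA
ASN	C	0.500	NA	NA	NA
ASN	O	-0.500	NA	NA	NA
ASN	CB	0.000	NA	NA	NA
ASN	CG	0.550	NA	NA	NA
ASN	OD1	-0.500	NA	NA	NA
ASN	ND2	-0.050	NA	NA	NA
GLN	N	-0.500	NA	NA	NA
GLN	CA	0.500	NA	NA	NA
GLN	C	0.500	NA	NA	NA
GLN	O	-0.500	NA	NA	NA
GLN	CB	0.000	NA	NA	NA
GLN	CG	0.000	NA	NA	NA
GLN	CD	0.550	NA	NA	NA
GLN	OE1	-0.500	NA	NA	NA
GLN	NE2	-0.050	NA	NA	NA
TYR	N	-0.500	NA	NA	NA
TYR	CA	0.500	NA	NA	NA
TYR	C	0.500	NA	NA	NA
TYR	O	-0.500	NA	NA	NA
TYR	CB	0.000	NA	NA	NA
TYR	CG	0.000	NA	NA	NA
TYR	CD1	0.000	NA	NA	NA
TYR	CD2	0.000	NA	NA	NA
TYR	CE1	0.000	NA	NA	NA
TYR	CE2	0.000	NA	NA	NA
TYR	CZ	0.250	NA	NA	NA
TYR	OH	-0.250	NA	NA	NA
TRP	N	-0.500	NA	NA	NA
TRP	CA	0.500	NA	NA	NA
TRP	C	0.500	NA	NA	NA
TRP	O	-0.500	NA	NA	NA
TRP	CB	0.000	NA	NA	NA
TRP	CG	0.000	NA	NA	NA
TRP	CD1	0.060	NA	NA	NA
TRP	CD2	0.000	NA	NA	NA
TRP	NE1	-0.060	NA	NA	NA
TRP	CE2	0.000	NA	NA	NA
TRP	CE3	0.000	NA	NA	NA
TRP	CZ2	0.000	NA	NA	NA
TRP	CZ3	0.000	NA	NA	NA
TRP	CH2	0.000	NA	NA	NA
HIS	N	-0.500	NA	NA	NA
HIS	CA	0.500	NA	NA	NA
HIS	C	0.500	NA	NA	NA
HIS	O	-0.500	NA	NA	NA
HIS	CB	0.000	NA	NA	NA
HIS	CG	0.100	NA	NA	NA
HIS	ND1	-0.300	NA	NA	NA
HIS	CD2	0.100	NA	NA	NA
HIS	CE1	0.300	NA	NA	NA
HIS	NE2	-0.200	NA	NA	NA
ASP	N	-0.500	NA	NA	NA
ASP	CA	0.500	NA	NA	NA
ASP	C	0.500	NA	NA	NA
ASP	O	-0.500	NA	NA	NA
ASP	CB	-0.100	NA	NA	NA
ASP	CG	0.450	NA	NA	NA
ASP	OD1	-0.675	NA	NA	NA
ASP	OD2	-0.675	NA	NA	NA
GLU	N	-0.500	NA	NA	NA
GLU	CA	0.500	NA	NA	NA
GLU	C	0.500	NA	NA	NA
GLU	O	-0.500	NA	NA	NA
GLU	CB	0.000	NA	NA	NA
GLU	CG	-0.100	NA	NA	NA
GLU	CD	0.450	NA	NA	NA
GLU	OE1	-0.675	NA	NA	NA
GLU	OE2	-0.675	NA	NA	NA
LYS	N	-0.500	NA	NA	NA
LYS	CA	0.500	NA	NA	NA
LYS	C	0.500	NA	NA	NA
LYS	O	-0.500	NA	NA	NA
LYS	CB	0.000	NA	NA	NA
LYS	CG	0.000	NA	NA	NA
LYS	CD	0.000	NA	NA	NA
LYS	CE	0.350	NA	NA	NA
LYS	NZ	0.650	NA	NA	NA
ARG	N	-0.500	NA	NA	NA
ARG	CA	0.500	NA	NA	NA
ARG	C	0.500	NA	NA	NA
ARG	O	-0.500	NA	NA	NA
ARG	CB	0.000	NA	NA	NA
ARG	CG	0.000	NA	NA	NA
ARG	CD	0.100	NA	NA	NA
ARG	NE	-0.100	NA	NA	NA
ARG	CZ	0.600	NA	NA	NA
ARG	NH1	0.200	NA	NA	NA
ARG	NH2	0.200	NA	NA	NA
MSE	N	-0.500	NA	NA	NA
MSE	CA	0.500	NA	NA	NA
MSE	C	0.500	NA	NA	NA
MSE	O	-0.500	NA	NA	NA
MSE	CB	0.000	NA	NA	NA
MSE	CG	0.100	NA	NA	NA
MSE	SE	-0.200	NA	NA	NA
MSE	CE	0.100	NA	NA	NA
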