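# Generic toy force-field parameters for H/C/N/O/Cl small molecules.
# Units: epsilon kcal/mol, sigma A, charge e, k(bond) kcal mol^-1 A^-2,
# r0 A, k(angle) kcal mol^-1 rad^-2, theta0 deg, v kcal/mol, phase deg.
# "X" is a wildcard for outer atoms of angles/torsions.
ATOMTYPES
H	0.0157	2.649	0
C	0.1094	3.3997	0
N	0.17	3.25	0
O	0.21	2.96	0
CL	0.265	3.47	0
BONDS
C	C	310	1.526
C	H	340	1.09
C	N	337	1.47
C	O	320	1.41
C	CL	232	1.79
N	H	434	1.01
O	H	553	0.96
ANGLES
H	C	H	35	109.471
C	C	C	63	111.0
X	C	X	50	109.471
X	N	X	50	109.471
X	O	X	55	104.5
TORSIONS
X	C	C	X	0.155	3	0
X	C	N	X	0.15	3	0
X	C	O	X	0.16	3	0
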