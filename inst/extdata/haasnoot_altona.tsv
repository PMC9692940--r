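# Generalized Karplus (Haasnoot-Altona 1980) coefficients for 3J(HH) across
# an H-C-C-H fragment, and Huggins group electronegativities relative to H.
# kind P     : curve coefficients (P6 in degrees, others Hz or dimensionless)
# kind dchi  : group electronegativity difference chi(X) - chi(H)
# kind sigma : prediction uncertainty of the curve (Hz)
kind	name	value
P	P1	13.70
P	P2	-0.73
P	P3	0.00
P	P4	0.56
P	P5	-2.47
P	P6	16.9
P	P7	0.14
dchi	H	0.00
dchi	C	0.40
dchi	N	0.85
dchi	O	1.30
dchi	F	1.70
dchi	Cl	0.95
dchi	S	0.45
dchi	Br	0.75
sigma	altona	0.6
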