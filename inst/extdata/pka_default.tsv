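# Default pKa set for charge-balance pI computation.
# free_* columns: alpha-carboxyl / alpha-amino / side-chain pKas of the free
#   amino acid (Lehninger tradition); used by the free_amino_acid mode.
# poly_pk_side: side-chain pKa inside a polypeptide (EMBOSS tradition);
#   Nterm / Cterm rows carry the terminal-group pKas for polypeptide mode.
# side_acidity: whether the side-chain group loses (acidic) or gains (basic)
#   a proton; NA for non-ionizable side chains.
residue	free_pk_carboxyl	free_pk_amino	free_pk_side	poly_pk_side	side_acidity
A	2.34	9.69	NA	NA	NA
R	2.17	9.04	12.48	12.5	basic
N	2.02	8.80	NA	NA	NA
D	1.88	9.60	3.65	3.9	acidic
C	1.96	10.28	8.18	8.5	acidic
E	2.19	9.67	4.25	4.1	acidic
Q	2.17	9.13	NA	NA	NA
G	2.34	9.60	NA	NA	NA
H	1.82	9.17	6.00	6.5	basic
I	2.36	9.68	NA	NA	NA
L	2.36	9.60	NA	NA	NA
K	2.18	8.95	10.53	10.8	basic
M	2.28	9.21	NA	NA	NA
F	1.83	9.13	NA	NA	NA
P	1.99	10.96	NA	NA	NA
S	2.21	9.15	NA	NA	NA
T	2.11	9.62	NA	NA	NA
W	2.38	9.39	NA	NA	NA
Y	2.20	9.11	10.07	10.1	acidic
V	2.32	9.62	NA	NA	NA
Nterm	NA	NA	NA	8.6	basic
Cterm	NA	NA	NA	3.6	acidic
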