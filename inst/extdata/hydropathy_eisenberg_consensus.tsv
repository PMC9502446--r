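# Eisenberg consensus hydrophobicity scale
# (Eisenberg, Weiss, Terwilliger & Wilcox, Faraday Symp Chem Soc 17:109-120, 1982).
residue	value
A	0.25
R	-1.76
N	-0.64
D	-0.72
C	0.04
Q	-0.69
E	-0.62
G	0.16
H	-0.40
I	0.73
L	0.53
K	-1.10
M	0.26
F	0.61
P	-0.07
S	-0.26
T	-0.18
W	0.37
Y	0.02
V	0.54
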