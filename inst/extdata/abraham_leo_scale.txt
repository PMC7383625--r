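# Signed per-residue hydrophobicity values (dimensionless), fragmental-constant
# variant attributed to Abraham & Leo (1987), as circulated in the ProtScale
# collection. Sign convention: hydrophobic residues positive, polar/charged
# residues negative. One record per canonical residue: LETTER VALUE.
A  0.44
R -2.42
N -1.32
D -0.31
C  0.58
Q -0.71
E -0.34
G  0.00
H -0.01
I  2.46
L  2.46
K -2.45
M  1.10
F  2.54
P  1.29
S -0.84
T -0.41
W  2.56
Y  1.63
V  1.73
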