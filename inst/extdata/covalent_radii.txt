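# Single-bond covalent radii (Angstrom), Cordero et al. consensus values,
# used for bond perception (bonded iff r < scale * (r_i + r_j)).
symbol radius
H  0.31
He 0.28
Li 1.28
Be 0.96
B  0.84
C  0.76
N  0.71
O  0.66
F  0.57
Ne 0.58
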