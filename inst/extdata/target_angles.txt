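# Target (ideal) hydrogen-bond angles per heteroatom environment.
# phi_target: ideal H...X-R1 bond angle (degrees).
# psi_targets: candidate ideal R1-R2-X...H torsions (degrees, ';'-separated);
# the candidate nearest the observed torsion is used.
# Provisional textbook values: tetrahedral environments 109.47/staggered,
# planar environments 120/in-plane.
element hybrid phi_target psi_targets
N sp3 109.47 120;-120
N sp2 120.00 0;180
O sp3 109.47 120;-120
O sp2 120.00 0;180
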