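# Hydrogen-bond correction parameters.
# c_n / c_o: strength parameters (Hartree Angstrom^2), grid-scan optimum.
# Damping constants are part of the functional form: bond damping on the
# donor-hydrogen distance (steepness 60, midpoint 1.2 A); donor-acceptor
# damping sigmoids (steepness 100 / midpoint 2.4 A and steepness 10 /
# midpoint 7.0 A). cutoff: term-enumeration limit on r_AB (A).
# unit_conversion: Hartree -> kcal/mol.
c_n -0.110
c_o -0.120
bond_steepness 60
bond_midpoint 1.2
damp_short_steepness 100
damp_short_midpoint 2.4
damp_long_steepness 10
damp_long_midpoint 7.0
cutoff 9.5
unit_conversion 627.509474
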