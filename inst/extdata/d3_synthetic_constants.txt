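# Constants of the SYNTHETIC dispersion reference dataset.
# k1: steepness of the coordination-number counting function.
# k3: Gaussian exponent of the C6 interpolation weights.
# r0_scale: cutoff radii rule r0_AB = r0_scale * sqrt(3 q_A q_B) (Bohr),
#   anchored so that the H-H cutoff radius equals 2.1823 Bohr.
k1 16
k3 -4
r0_scale 0.627672
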