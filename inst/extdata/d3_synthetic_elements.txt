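# SYNTHETIC dispersion reference dataset for elements H-Ne.
# This table is assembled from published scalar constants and documented
# combination rules; it is NOT the original CN-interpolated C6 reference
# grid of the third-generation dispersion scheme (see the methods
# vignette for the construction and its consequences).
#
# rcov: single-bond covalent radii (Angstrom, Pyykko/Atsumi) entering the
#   coordination-number counting function (which applies the 4/3 scale).
# q: effective sqrt(<r^4>/<r^2>) factors (atomic units, include the
#   sqrt(Z) scaling) for the C8 recursion C8 = 3 C6 q_A q_B.
# c6_free: free-atom C6 coefficient (a.u.), reference point at CN = 0.
# c6_valence, cn_valence: in-molecule C6 coefficient (a.u., converted
#   from the published J nm^6/mol molecular values; factor 17.3458) at a
#   nominal valence coordination number. NA: single-reference element.
symbol rcov q c6_free c6_valence cn_valence
H  0.32 2.00734898    7.59    2.4284 1
He 0.46 1.56637132    1.46        NA NA
Li 1.33 5.01986934 1387.00   27.9267 1
Be 1.02 3.85379032  214.00   27.9267 2
B  0.85 3.64446594   99.50   54.2924 3
C  0.75 3.10492822   49.10   30.3552 4
N  0.71 2.71175247   25.30   21.3353 3
O  0.63 2.59361680   15.50   12.1421 2
F  0.64 2.38825250    9.69    9.6900 1
Ne 0.67 2.21522516    6.29        NA NA
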