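# Default geometry reference windows (Angstrom for bonds, degrees for angles).
# Generous mean +/- 4-sigma style windows per feature class; replaceable by a
# user CSV with the same columns for stricter, library-derived checks.
feature_class,min,max
bond.C-C,1.40,1.65
bond.C:C,1.32,1.47
bond.C=C,1.25,1.42
bond.C%C,1.14,1.26
bond.C-H,0.95,1.15
bond.C-N,1.30,1.56
bond.C:N,1.27,1.43
bond.C=N,1.20,1.36
bond.C%N,1.08,1.22
bond.C-O,1.28,1.52
bond.C=O,1.14,1.30
bond.C-S,1.68,1.92
bond.C:S,1.62,1.82
bond.C=S,1.55,1.72
bond.C-F,1.28,1.45
bond.C-Cl,1.62,1.85
bond.C-Br,1.80,2.02
bond.C-I,2.00,2.25
bond.H-N,0.95,1.12
bond.H-O,0.88,1.06
bond.H-S,1.22,1.48
bond.N-N,1.28,1.52
bond.N:N,1.24,1.42
bond.N=N,1.18,1.35
bond.N-O,1.30,1.52
bond.N=O,1.14,1.32
bond.O-S,1.40,1.66
bond.O=S,1.36,1.55
bond.S-S,1.90,2.15
bond.N-S,1.55,1.80
bond.O-O,1.35,1.55
angle.C2,150,180
angle.C3,102,138
angle.C4,92,128
angle.N1,150,180
angle.N2,98,142
angle.N3,95,132
angle.N4,98,122
angle.O2,92,125
angle.S2,82,112
angle.S3,88,115
angle.S4,95,125
angle.P4,95,125
torsion.any,-180,180
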