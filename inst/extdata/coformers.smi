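# GRAS coformer short-list used in the experimental screen (SMILES, name)
C1=CC2=C(C=C1)N=C(N2)C3=CSC=N3 thiabendazole
C1=CC(=CC=C1C2=COC3=CC(=CC(=C3C2=O)O)O)O genistein
COC1=C(C=C(C=C1)C2CC(=O)C3=C(C=C(C=C3O2)O)O)O hesperitin
C1=CC(=CN=C1)C(=O)N nicotinamide
CCOC(=O)C1=CC=C(C=C1)O ethylparaben
C1C2C(C(S1)CCCCC(=O)O)NC(=O)N2 biotin
C1=CC=C2C(=C1)C=C(C(=C2CC3=C(C(=CC4=CC=CC=C43)C(=O)O)O)O)C(=O)O pamoic_acid
C1=CC=C(C=C1)C(C(=O)O)O dl_mandelic_acid
C1=CC(=CC=C1CC(C(=O)O)N)O l_tyrosine
C1=CC=C2C(=C1)C(=CN2)CC(C(=O)O)N l_tryptophan
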