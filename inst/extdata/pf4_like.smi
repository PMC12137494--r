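# Synthetic flexible API stand-in (the published API structure is not part of
# this package). Carries the motifs the screen exercises: a carboxamide
# donor/acceptor pair, an aromatic nitrogen acceptor, an aryl ether linker and
# several rotatable bonds for a genuine conformer ensemble.
CC(C)(C(=O)N)c1ccc(Oc2ccc(cc2)-c2ccncc2)cc1 pf4_like_synthetic
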