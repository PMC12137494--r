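# Reference metadata for the API base form, as published.
# dipole_debye was computed with the original study's charge model; the
# package's Gasteiger-based dipole is a different model and is NOT expected
# to reproduce it. Carried as fixture metadata only.
api: pf4_like_synthetic
published_api: PF-04191834
dipole_debye: 6.434
n_conformers_default: 9
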