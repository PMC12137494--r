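# Complementarity-screen facts quoted in the published prose (the refined
# top-16 table itself is printed only as a figure). complementarity_rank is
# the position on the initial complementarity screen where stated; pass_note
# records pass counts quoted in prose.
coformer,complementarity_rank,pass_note,note
thiabendazole,1,,lowest optimal deviancy of the screen; max interaction 0.28
hesperitin,2,,ranked 2nd overall on the initial complementarity screen
l_tyrosine,4,,moved up for high hydrogen-bond propensity
l_tryptophan,7,,moved up for high hydrogen-bond propensity
ethylparaben,8,,tendency to form heterosynthons with coformer donating
nicotinamide,22,,high polar fraction hurt complementarity rank
dl_mandelic_acid,NA,passed 6 of 10 conformations,dipole delta out of range in 4 conformations
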