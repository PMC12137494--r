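# Jet-dispensing screening trials transcribed from the published summary table.
# One row per trial. max_interaction and multicomponent_score both carry the
# single printed per-coformer value (the published table prints one number per
# coformer next to the bonding direction). Trial ids F37-F39 are absent from
# the available text, which prints 42 trials and 8 positives in prose;
# DL-mandelic acid is therefore transcribed as four trials (all negative),
# matching those totals. outcome: TRUE = evidence of cocrystallisation by DSC.
trial,coformer,direction,max_interaction,multicomponent_score,optimal_deviancy,solvent,ratio,outcome
F1,thiabendazole,api_to_coformer,0.28,0.28,25.7,ACN:EtOH,1:1,TRUE
F2,thiabendazole,api_to_coformer,0.28,0.28,25.7,ACN:EtOH,1:1.1,TRUE
F3,thiabendazole,api_to_coformer,0.28,0.28,25.7,ACN:EtOH,2:1,FALSE
F4,thiabendazole,api_to_coformer,0.28,0.28,25.7,ACN:EtOH,1:2,FALSE
F5,biotin,both,0.12,0.12,40.1,EtOH:DMSO,1:1,FALSE
F6,biotin,both,0.12,0.12,40.1,EtOH:DMSO,1:1.1,FALSE
F7,biotin,both,0.12,0.12,40.1,EtOH:DMSO,2:1,FALSE
F8,biotin,both,0.12,0.12,40.1,EtOH:DMSO,1:2,FALSE
F9,genistein,api_to_coformer,0.06,0.06,33.6,ACN:EtOH,1:1,TRUE
F10,genistein,api_to_coformer,0.06,0.06,33.6,ACN:EtOH,1:1.1,TRUE
F11,genistein,api_to_coformer,0.06,0.06,33.6,ACN:EtOH,2:1,TRUE
F12,genistein,api_to_coformer,0.06,0.06,33.6,ACN:EtOH,1:2,TRUE
F13,l_tyrosine,coformer_to_api,0.05,0.05,32.9,ACN:DMSO,1:1,FALSE
F14,l_tyrosine,coformer_to_api,0.05,0.05,32.9,ACN:DMSO,1:1.1,FALSE
F15,l_tyrosine,coformer_to_api,0.05,0.05,32.9,ACN:DMSO,2:1,FALSE
F16,l_tyrosine,coformer_to_api,0.05,0.05,32.9,ACN:DMSO,1:2,FALSE
F17,nicotinamide,api_to_coformer,0.05,0.05,45.5,EtOH:DMSO,1:1,FALSE
F18,nicotinamide,api_to_coformer,0.05,0.05,45.5,EtOH:DMSO,1:1.1,FALSE
F19,nicotinamide,api_to_coformer,0.05,0.05,45.5,EtOH:DMSO,2:1,FALSE
F20,nicotinamide,api_to_coformer,0.05,0.05,45.5,EtOH:DMSO,1:2,FALSE
F21,l_tryptophan,coformer_to_api,0.03,0.03,33.8,ACN:DMSO,1:1,FALSE
F22,l_tryptophan,coformer_to_api,0.03,0.03,33.8,ACN:DMSO,1:1.1,FALSE
F23,l_tryptophan,coformer_to_api,0.03,0.03,33.8,ACN:DMSO,2:1,FALSE
F24,l_tryptophan,coformer_to_api,0.03,0.03,33.8,ACN:DMSO,1:2,FALSE
F25,ethylparaben,coformer_to_api,0.02,0.02,34.9,EtOH:DMSO,1:1,FALSE
F26,ethylparaben,coformer_to_api,0.02,0.02,34.9,EtOH:DMSO,1:1.1,FALSE
F27,ethylparaben,coformer_to_api,0.02,0.02,34.9,EtOH:DMSO,2:1,FALSE
F28,ethylparaben,coformer_to_api,0.02,0.02,34.9,EtOH:DMSO,1:2,FALSE
F29,hesperitin,api_to_coformer,0.01,0.01,31,ACN:EtOH,1:1,TRUE
F30,hesperitin,api_to_coformer,0.01,0.01,31,ACN:EtOH,1:1.1,TRUE
F31,hesperitin,api_to_coformer,0.01,0.01,31,ACN:EtOH,2:1,FALSE
F32,hesperitin,api_to_coformer,0.01,0.01,31,ACN:EtOH,1:2,FALSE
F33,pamoic_acid,coformer_to_coformer,-0.05,-0.05,35.9,PYR:DMSO,1:1,FALSE
F34,pamoic_acid,coformer_to_coformer,-0.05,-0.05,35.9,PYR:DMSO,1:1.1,FALSE
F35,pamoic_acid,coformer_to_coformer,-0.05,-0.05,35.9,PYR:DMSO,2:1,FALSE
F36,pamoic_acid,coformer_to_coformer,-0.05,-0.05,35.9,PYR:DMSO,1:2,FALSE
F37,dl_mandelic_acid,api_to_coformer,0.51,0.51,41.1,EtOH:DMSO,1:1.1,FALSE
F38,dl_mandelic_acid,api_to_coformer,0.51,0.51,41.1,EtOH:DMSO,2:1,FALSE
F39,dl_mandelic_acid,api_to_coformer,0.51,0.51,41.1,EtOH:DMSO,1:2,FALSE
F40,dl_mandelic_acid,api_to_coformer,0.51,0.51,41.1,EtOH:DMSO,1:1,FALSE
F41,nicotinamide,api_to_coformer,0.05,0.05,45.5,EtOH:DMSO,3:1,FALSE
F42,nicotinamide,api_to_coformer,0.05,0.05,45.5,EtOH:DMSO,4:1,FALSE
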