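# Example complementarity cutoff configuration.
# dipole_delta_max and fpv_delta_max are the published polarity cutoffs; the
# geometric cutoffs below are illustrative round values (the published table
# of geometric cutoffs is not reproduced in the available text) and should be
# replaced with study-specific limits.
dipole_delta_max: 5.94
fpv_delta_max: 0.294
ml_ratio_delta_max: 0.25
sl_ratio_delta_max: 0.25
s_axis_delta_max: 2.5
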