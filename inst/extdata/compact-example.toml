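# Example configuration for `mcdem compact`: 150-particle bed of the
# reference MCC excipient, compacted to 57% strain with the multi-contact
# elastic-plastic law.
n = 150
target_strain = 0.57
beta = 1.3
k2_ratio = 5
k1_scale = 1.9
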