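# Example run configuration: keys mirror model_params() arguments, plus
# the seed bundle and a size preset. Unspecified keys take the published
# defaults.
preset: small
L: 2
map_seed: 1
dynamics_seed: 1
velocity_seed: 1
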