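# Demo pipeline configuration. Any key omitted here falls back to
# default_config(); unknown keys are rejected at load.
seed: 1
scenario: unamended
replicates: 3
noise_cv: 0.05
dt: 0.1
split_temp: 43
pairing: max
ph: 7.5
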