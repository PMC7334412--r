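# Example cohort configuration: a small healthy-donor cohort with the
# CD56neg NKp80+ compartment doubled relative to the preset.
condition: HD
n_donors: 3
n_events: 5000
seed: 7
abundance_jitter: 2000
abundance_overrides:
  NK_neg_CD16pos: 0.0035
  NK_neg_CD16neg: 0.0035
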