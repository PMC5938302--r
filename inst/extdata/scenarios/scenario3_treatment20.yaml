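name: treatment20
start_date: '2017-01-01'
overrides:
  treatment_coverage: 0.2
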