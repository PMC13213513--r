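# Demo run: small templated synthetic ensemble, full analysis chain.
ensemble:
  source: generate
  kind: templated
  n_frames: 12
  n_solutes: 8
  templating_strength: 3
  modifier_size: 3
seed: 7
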