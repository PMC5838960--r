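components:
- liver
- brain
- placenta
mixtures:
  mix1:
  - 0.25
  - 0.25
  - 0.5
  mix2:
  - 0.25
  - 0.5
  - 0.25
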