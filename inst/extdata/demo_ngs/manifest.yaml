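samples:
- sample_id: liver_r1
  role: pure:liver
  replicate: 1
  round: round1
- sample_id: liver_r2
  role: pure:liver
  replicate: 2
  round: round1
- sample_id: liver_r3
  role: pure:liver
  replicate: 3
  round: round1
- sample_id: brain_r1
  role: pure:brain
  replicate: 1
  round: round1
- sample_id: brain_r2
  role: pure:brain
  replicate: 2
  round: round1
- sample_id: brain_r3
  role: pure:brain
  replicate: 3
  round: round1
- sample_id: placenta_r1
  role: pure:placenta
  replicate: 1
  round: round1
- sample_id: placenta_r2
  role: pure:placenta
  replicate: 2
  round: round1
- sample_id: placenta_r3
  role: pure:placenta
  replicate: 3
  round: round1
- sample_id: mix1_r1
  role: mix:mix1
  replicate: 1
  round: round1
- sample_id: mix1_r2
  role: mix:mix1
  replicate: 2
  round: round1
- sample_id: mix1_r3
  role: mix:mix1
  replicate: 3
  round: round1
- sample_id: mix2_r1
  role: mix:mix2
  replicate: 1
  round: round1
- sample_id: mix2_r2
  role: mix:mix2
  replicate: 2
  round: round1
- sample_id: mix2_r3
  role: mix:mix2
  replicate: 3
  round: round1
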