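schema: fibrolink/v1
kind: fibroblast_params
params:
  cf: 50.0
  nf: 8.0
  gkv: 0.25
  gk1: 0.4822
  gbna: 0.0095
  inak_max: 2.002
  kmk: 1.0
  kmna: 11.0
  vrev: -150.0
  ki: 129.434899999999999
  nai: 8.5547
  ko: 5.3581
  nao: 130.010999999999996
  kv_shift: 0.1885093042557
  vfr: hyperpolarized
  vfr_target: -49.0

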