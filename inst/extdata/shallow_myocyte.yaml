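schema: fibrolink/v1
kind: myocyte_params
params:
  gna: 14.837999999999999
  gk1: 5.405
  gto: 0.294
  gkr: 0.153
  gks: 0.392
  gcal: 3.98e-05
  gbna: 0.00029
  gbca: 0.000592
  gpca: 0.1238
  gpk: 0.0146
  p_nak: 2.724
  k_naca: 1000.0
  tauf_scale: 0.5
  cm: 150.0
  ko: 5.4
  nao: 140.0
  cao: 2.0
  variant: shallow

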