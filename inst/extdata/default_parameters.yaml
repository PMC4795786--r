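units:
  concentration: uM
  time: s
rate_constants:
  k1: 0.04
  k2: 8.0
  k3: 0.1
  k4: 0.0005
  k5: 0.01
  k6: 0.01
  k7: 0.1
  k8: 0.05
  k9: 10.0
  k10: 2.5
  k11: 0.1
  k12: 3.0
  k13: 1.8
initial_concentrations:
  H2O2: 0.0
  sGC: 0.2
  sGC_H2O2: 0.0
  'NO': 0.5
  NO_sGC: 0.0
  GTP: 50.0
  sGC_GTP: 0.0
  NO_sGC_GTP: 0.0
  cGMP: 0.0
  PDE: 0.08
  cGMP_PDE: 0.0
  GMP: 0.0
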