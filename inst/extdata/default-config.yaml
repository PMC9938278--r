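# Reference configuration: every biophysical constant, burst-sorting
# threshold and integration default of the SAC wave model, written out
# explicitly. Loading this file is identical to loading an empty one.
parameters:
  V1: -20.0
  V2: 20.0
  V3: -25.0
  V4: 7.0
  V0e: -40.0
  Vse: 0.2
  V0i: -40.0
  Vsi: 0.2
  V7: 10.0
  V8: -40.0
  V9: 10.0
  V10: 4.0
  V11: -65.0
  V12: 18.0
  V13: 0.07
  V14: -65.0
  V15: 20.0
  V16: 1.0
  V17: -35.0
  V18: 10.0
  Cm: 17.0
  gLeak: 2.0
  gCa: 8.5
  gK: 4.0
  gNa: 2.0
  gTREK: 2.0
  gACh: 0.215
  gGABA: 0.9
  sigma: 5.0
  ELeak: -70.0
  ECa: 50.0
  EK: -90.0
  ENa: 55.0
  EACh: 0.0
  ECl: -65.0
  tauN: 5.0
  tauA: 8300.0
  tauB: 8300.0
  tauC: 2000.0
  tauACh: 540.0
  tauGABA: 1000.0
  tauW: 1000.0
  C0: 0.088
  lambda: 2.702
  delta: 0.010503
  alpha: 625.0
  beta: 34.0
  rho_e: 6.0
  rho_i: 5.0
  Kd: 0.1
  De: 0.005
  Di: 0.005
  dXe: [1.0, 1.0]
  dYe: [1.0, 1.0]
  dXi: [1.0, 1.0]
  dYi: [1.9, 0.1]
  Iapp: 0.0
burst:
  ISI_start: 500
  ISI_end: 500
  IBI_min: 1000
  Duration_min: 100
  SPB_min: 4
lattice:
  nx: 64
  ny: 64
integration:
  dt: 0.05
  t_end: 300000
  save_every: 1
seed: 1
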