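M0: 1.0e+08
gamma_max: 1260.0
K_gamma: 7.0
ns: 0.5
d_m: 0.1
d_p: 0.0
kb: 1.0
ku: 1.0
w:
  T: 4.14
  E: 4.14
  Ep: 4.14
  Tp: 4.14
  TF: 4.14
  X: 948.93
  R: 930.0
theta:
  T: 4.38
  E: 4.38
  Ep: 4.38
  Tp: 4.38
  TF: 4.38
  X: 4.38
  R: 426.87
'n':
  T: 300.0
  E: 300.0
  Ep: 300.0
  Tp: 300.0
  TF: 300.0
  X: 300.0
  R: 7549.0
kcat:
  T: 726.0
  E: 5800.0
  Ep: 5800.0
  Tp: 726.0
  X: 0.01
Km:
  T: 1.0e+09
  E: 1000.0
  Ep: 1000.0
  Tp: 1000.0
  X: 1000.0
v_ind: 1000.0
Km_ind: 1000000.0
K_ind_tf: 10.0
Kq_X: 152200.0
hq_X: 4.0
leak: 0.001
drain_point: metabolite
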