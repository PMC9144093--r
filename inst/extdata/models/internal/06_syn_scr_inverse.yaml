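# synthetic stand-in model
name: syn_scr_inverse
label: 6
parameters:
  CL: "2.6 * (0.8 / scr)^0.61"
  V1: "0.47 * weight"
  Q: "6.9"
  V2: "35"
omega:
  names: [CL, V1, Q]
  values: [0.05, 0.0, 0.03, 0.0, 0.0, 0.08]
residual: {add: 0.4, prop: 0.25}
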