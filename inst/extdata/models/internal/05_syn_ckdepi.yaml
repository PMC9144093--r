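# synthetic stand-in model
name: syn_ckdepi
label: 5
parameters:
  CL: "3.3 * (ckdepi / 95)^0.82"
  V1: "33"
  Q: "9.8"
  V2: "66"
omega:
  names: [CL, V1]
  values: [0.12, 0.0, 0.10]
residual: {add: 1.6, prop: 0.17}
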