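# synthetic stand-in model
name: syn_mdrd
label: 3
parameters:
  CL: "2.9 * (mdrd / 90)^0.64"
  V1: "0.39 * weight"
  Q: "8.6"
  V2: "57"
omega:
  names: [CL, V1, V2]
  values: [0.07, 0.0, 0.04, 0.0, 0.0, 0.10]
residual: {add: 1.3, prop: 0.15}
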