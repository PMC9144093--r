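# synthetic stand-in model
name: syn_flat
label: 9
parameters:
  CL: "3.1"
  V1: "0.50 * weight"
  Q: "7.7"
  V2: "52"
omega:
  names: [CL, V1]
  values: [0.15, 0.0, 0.06]
residual: {add: 0.7, prop: 0.21}
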