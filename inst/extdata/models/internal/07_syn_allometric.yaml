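# synthetic stand-in model
name: syn_allometric
label: 7
parameters:
  CL: "3.6 * (weight / 65)^0.75 * (crcl / 95)^0.52"
  V1: "0.36 * weight"
  Q: "11.1"
  V2: "73"
omega:
  names: [CL, V1]
  values: [0.08, 0.0, 0.07]
residual: {add: 0.9, prop: 0.19}
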