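name: toy_mid
label: 2
parameters:
  CL: "3.2 * (crcl / 100)^0.75"
  V1: "0.55 * weight"
  Q: "6"
  V2: "55"
omega:
  names: [CL, V1]
  values: [0.08, 0.0, 0.05]
residual: {add: 1.0, prop: 0.2}
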