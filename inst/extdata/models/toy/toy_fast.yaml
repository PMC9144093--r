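name: toy_fast
label: 1
parameters:
  CL: "6.5 * (crcl / 100)"
  V1: "0.35 * weight"
  Q: "8"
  V2: "35"
omega:
  names: [CL, V1]
  values: [0.06, 0.0, 0.04]
residual: {add: 0.5, prop: 0.15}
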