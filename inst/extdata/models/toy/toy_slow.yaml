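name: toy_slow
label: 3
parameters:
  CL: "1.3 + 0.004 * crcl"
  V1: "45"
  Q: "4"
  V2: "80"
omega:
  names: [CL, V1]
  values: [0.05, 0.0, 0.06]
residual: {add: 0.8, prop: 0.18}
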