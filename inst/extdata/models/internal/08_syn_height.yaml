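# synthetic stand-in model
name: syn_height
label: 8
parameters:
  CL: "0.02 * crcl + 0.006 * height"
  V1: "0.26 * height"
  Q: "4.4"
  V2: "41"
omega:
  names: [CL, V1, V2]
  values: [0.11, 0.0, 0.09, 0.0, 0.0, 0.14]
residual: {add: 1.1, prop: 0.16}
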