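# synthetic stand-in model: hemodialysis population
name: syn_hd
label: 3
parameters:
  CL: "0.4 + 0.035 * crcl * (1 - hd)"
  V1: "0.45 * weight"
  Q: "5.5"
  V2: "70"
omega:
  names: [CL, V1]
  values: [0.16, 0.0, 0.09]
residual: {add: 1.0, prop: 0.22}
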